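Package: fedseg
Title: Desk-Scale Federated Deep Learning for Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-process, fully testable re-creation of a Personal Health
    Train style federated deep learning infrastructure for binary tumor
    segmentation: a central coordinating server (entity registry, pull-based
    task distribution, final-model-only persistence), a secure aggregation
    server performing synchronous FedAvg behind per-iteration JSON Web Tokens,
    data-station workers that train a small 2D U-Net locally, and a
    deterministic multi-site CT-phantom generator producing horizontally
    partitioned NIfTI image/mask cohorts. Includes bit-exact weight
    serialization, dropout recovery from the latest successful model, an
    instrumented in-memory transport for privacy audits, and an end-to-end
    federation simulator with per-iteration Dice/loss history export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    openssl,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'RcppExports.R'
    'weights.R'
    'unet.R'
    'train.R'
    'phantom.R'
    'tokens.R'
    'transport.R'
    'aggregator.R'
    'coordinator.R'
    'station.R'
    'federation.R'
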