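---
title: "Federated tumor segmentation at desk scale: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated tumor segmentation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package simulates

Hospitals cannot pool CT images, but they can pool models. In the
federated-learning architecture this package implements, a segmentation
network travels to the data: a **central coordinating server** registers
every participant (researcher, data stations, aggregator), stores task
metadata and distributes work through a pull mechanism; a **secure
aggregation server** (SAS) runs the master algorithm, averages the locally
trained models, and keeps every intermediate model isolated from the
coordinator, the researcher, and anyone without a station token; and **data
stations** hold the images, train locally, and exchange only model weights.
All of it runs here in one R process over an instrumented in-memory
transport, with a deterministic CT-phantom generator standing in for the
clinical data, so every protocol guarantee is testable on a desk.

`simulateFederation()` drives the full lifecycle: registration and
password authentication, researcher task submission, master/subtask
distribution, the synchronous iteration loop, dropout recovery,
finalization, and the researcher's download of the single final model.

## The model and its training

The "train" payload is a small 2D U-Net: `depth` encoder levels of two 3x3
convolutions (ReLU) followed by 2x2 max pooling, a two-convolution
bottleneck, and a mirrored decoder using nearest-neighbour upsampling, a
3x3 convolution, and concatenated skip connections, closed by a 1x1
convolution with a sigmoid. The default `modelConfig()` (depth 2, 8 base
filters, 64x64 inputs) has 32,521 parameters — deliberately tiny; the
architecture family, not its capacity, is the point. Forward and backward
passes are written in package code on top of BLAS matrix products, with the
im2col gather/scatter in compiled C++; gradients are pinned against central
finite differences in the test suite.

Training minimizes, by default, an equal blend of binary cross-entropy and
the soft-Dice loss `1 - (2 sum(p g) + s) / (sum(p) + sum(g) + s)`
(smoothing `s = 1`), using Adam (learning rate `5e-4`, betas 0.9/0.999) on
minibatches of 2. Pure soft Dice (`loss_name = "dice_loss"`) is available
and is the loss most directly matched to the reported metric, but it was
deliberately not made the default after it proved fragile in federation:
Dice-only training has an *absorbing* failure state. Early Adam steps —
whose per-parameter magnitude is `lr` regardless of gradient size, and
which are largest right after an averaging round resets the optimizer
moments on averaged weights — can knock the model into predicting
all-background; once the sigmoid saturates hard enough that probabilities
underflow to exactly zero, the Dice gradient is identically zero and the
run never recovers (observed as validation Dice dropping to 0 permanently
mid-federation, at more than one learning rate and seed). The
cross-entropy term removes the absorbing state: its gradient `(p - g)` is
alive at saturation, so the same transient collapses self-correct within
an iteration or two. The conservative learning-rate default makes such
excursions rare in the first place. A *step* is one minibatch gradient update — task
configurations count steps, not epochs, and a task's
`steps_per_iteration` overrides the station default. Optimizer state is
local to an iteration: every federated round restarts Adam from zero on
the incoming global model, which keeps the exchanged unit a pure
`WeightSet` and makes a K=1 federation provably identical to a plain
centralized loop.

Inference thresholds the sigmoid probabilities at 0.5 by default. The Dice
score of two empty masks is defined as 1.0 (a correct rejection); this
convention matters on phantoms only in degenerate configurations, since the
generator guarantees a non-empty tumor in every case.

## FedAvg and the synchronous barrier

The global update is federated averaging: with station models `w_k` trained
on `n_k` local samples, the aggregated model is the parameter-wise convex
combination `w = sum_k (n_k / n) w_k`. Sample weighting is the default;
`uniform` is available by configuration. The SAS holds a strict barrier —
averaging runs only when every rostered station has submitted, exactly
once per iteration, in roster order regardless of arrival order, so results
are independent of submission timing. A second submission from the same
station in one iteration is refused (first wins): the simplest auditable
policy.

The SAS also creates the initial model (`initWeights`, He-normal, seeded
from the task's `model_seed`) and broadcasts it as "iteration 0's previous
model", so all stations start from identical bytes — the synchronization
step the protocol needs but deployment descriptions usually leave implicit.

## Per-iteration tokens

Every station-SAS exchange carries a JSON Web Token (HMAC-SHA-256,
compact serialization) with claims `(station, task, iteration, issued_at,
expires_at)`. The signing key is a per-task symmetric secret generated by
the coordinator at task submission and delivered only inside the
aggregator's master work item. The SAS mints tokens when an iteration
opens (and re-mints on re-open after an abort; superseded tokens are
revoked via an allowlist, so a captured pre-abort token is a replay even
though its claims still match). Validation checks, in order: structure,
signature, station roster membership, task, iteration, and the validity
window with a 30 s clock-skew allowance; each failure raises a typed
rejection (`tokenForgery`, `tokenIntegrity`, `tokenReplay`, `tokenExpiry`)
and has no side effects on aggregation state. Default lifetime is 7200 s —
roughly twice a realistic iteration wall time. Iterations are 0-based
everywhere.

Payload encryption is delegated to the transport (HTTPS in a deployment;
a trusted in-process bus here), and asymmetric keys or rotation
infrastructure are out of scope.

## Isolation and persistence rules

Three invariants define the privacy posture, and all three are enforced in
code and asserted in tests:

* **Data locality.** No station operation places image or mask arrays on
  the transport; the instrumented transport records a recursive inventory
  of every payload, and `auditTransportLog()` flags phantom cases, fields
  named like images, or anonymous numeric arrays of image size.
* **Intermediate-model isolation.** The only route to an intermediate model
  is `releaseGlobalModel` with a valid current-iteration station token.
  The coordinator has no such route; a researcher's `fetchFinalModel` is
  denied (not "not found") until the task finishes.
* **Final-model-only persistence.** The coordinator stores zero WeightSets
  for unfinished tasks and exactly one per finished task
  (`storedModelCount()` audits this), and the status-report channel
  refuses any payload containing weights.

Dropouts follow an abort-and-reopen policy: on a station failure the open
iteration's partial submissions are discarded, the same iteration reopens
with fresh tokens, and the latest successful model — which is never rolled
back — seeds the retry. Whether a real deployment would instead skip the
failed station is an open choice; abort-and-reopen was selected because it
preserves the synchronous all-stations semantics of the averaging step.
The station side retries transient aggregator outages three times with
exponential backoff before filing an abort report. Work items leased from
the coordinator re-queue after a 10-minute lease timeout.

## The phantom generator

Each site profile describes one simulated hospital: patient count, an
additive grey-level calibration offset, a noise standard deviation, a tumor
radius range, lung-ellipse semi-axes, a grid, and a seed. A case is a dark
background (grey level 20), a brighter lung ellipse (60), and one
quasi-elliptical tumor blob (140) with area-preserving axis jitter (up to
±20%), random rotation and smooth low-frequency boundary perturbation,
plus the site offset and Gaussian noise; the mask is the tumor blob,
guaranteed non-empty and inside the lung. Every case is a pure function of
`(site seed, case index)`, so cohorts regenerate bit-identically and
adding patients never perturbs existing ones. Patient identifiers embed
the site id, which makes horizontal partitioning (disjoint subjects across
sites) structural rather than conventional. Validation splits reserve
`max(1, round((1 - split) n))` cases; a one-patient site is rejected
because every station must validate locally.

The default study conditions are three heterogeneous sites of 50 patients
each (40 train / 10 validation at the 0.8 split) with offsets {0, +18,
−12}, noise SDs {4, 6, 8}, and slightly different tumor-size ranges and
lung geometries — enough cross-site shift to make federation non-trivial
while remaining learnable by the tiny U-Net in minutes of CPU time. The
slice size and intensity scale of real preprocessed CT are not dictated by
the deployment this emulates, so 64x64 single slices with grey levels on a
0–150 scale (network inputs divided by 150) were fixed once as free
choices. What the phantoms deliberately do **not** emulate: 3D anatomy,
DICOM idiosyncrasies, HU calibration, registration error, multiple or
absent tumors, and class-imbalance extremes of clinical GTV segmentation —
so a passing suite demonstrates protocol correctness and trainability, not
clinical accuracy.

Cases are exchanged with disk as NIfTI-1 pairs (image float32, mask uint8,
identity affine) in the station layout
`site_<id>/{train,validation}/<patient>_{img,msk}.nii.gz`.

## Numerical choices

R has no 32-bit float type, so all weight values and phantom intensities
are defined on the IEEE float32 grid: `float32()` quantizes on
construction of every `WeightSet` and phantom image, making the 4-byte
payload of the `.fweights` container and float32 NIfTI files bit-exact
round trips of the in-memory doubles. The container is a JSON manifest
(names, shapes, counts, byte offsets, SHA-256 payload digest) followed by
the little-endian float32 payload; digest, length and dtype are verified
before any object is constructed.

Determinism is by construction rather than by flags: all randomness flows
through isolated, explicitly seeded Mersenne-Twister streams
(`withSeed()`), per-case and per-iteration seeds are derived with fixed
multipliers so streams never collide, and aggregation iterates stations in
roster order. Two runs of `simulateFederation()` with the same
configuration produce identical final weights and identical histories
(wall-clock columns aside). Max-pool ties break to the first index;
ReLU subgradients at exactly zero take the zero branch — both relevant
only on measure-zero configurations, and only the tie-break is observable
(at freshly initialized, zero-bias models).

## Desk-scale problem sizes

The test suite exercises most contracts on a 32x32 grid with a
depth-2/base-4 network and single-digit step counts, which keeps the whole
non-acceptance suite under half a minute. The acceptance-scale checks use
the sizes the guarantees are stated at: 100+ fuzz cases for averaging and
token security, a 3-iteration x 50-step single-station run for the
federated-equals-centralized identity, and the full default study — three
64x64 sites, 10 iterations x 100 steps of the depth-2/base-8 U-Net — for
the learning-progress check, where mean validation Dice of the incoming
global model must rise over the run and the final model must exceed 0.6
mean Dice on held-out validation patients. `scripts/acceptance.R` reruns
that study end to end and reports the measured quantities.

## Known limitations

* Single-process in-memory transport only; the HTTP deployment surface
  (API forwarder port 5050 proxying an algorithm API on port 7000) is
  recorded in the configuration schema but not served.
* Synchronous FedAvg only — no asynchronous or ensemble schemes, no
  differential privacy, no homomorphic encryption.
* The optional early-stopping rule (stop when mean validation Dice
  improves by less than 0.002 over three consecutive iterations) is not
  enabled by default; runs execute their configured iteration count.
* Coordinator persistence is in-memory with an optional JSON-lines event
  journal; there is no crash-recovery write-ahead log.
* The phantom task is far easier than clinical GTV segmentation; Dice
  numbers here say nothing about performance on real CT.
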