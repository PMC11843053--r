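## Local training loop, inference and the Dice metric.

PHANTOM_NORM <- 150   # grey-level scale applied to network inputs

## Soft-Dice (optionally blended with BCE) loss over a whole minibatch.
## Returns the scalar loss and its gradient wrt the pre-sigmoid logits z.
lossAndGradZ <- function(z, p, g, loss_name, smooth = 1) {
  S <- sum(p) + sum(g) + smooth
  I2 <- 2 * sum(p * g) + smooth
  dice <- 1 - I2 / S
  dpDice <- -(2 * g * S - I2) / S^2
  dzDice <- dpDice * p * (1 - p)
  if (loss_name == "dice_loss") return(list(loss = dice, dz = dzDice))
  n <- length(p)
  eps <- 1e-12
  bce <- -mean(g * log(p + eps) + (1 - g) * log(1 - p + eps))
  dzBce <- (p - g) / n
  list(loss = 0.5 * bce + 0.5 * dice, dz = 0.5 * dzBce + 0.5 * dzDice)
}

checkManifestAgainstConfig <- function(w, config) {
  exp <- expectedManifest(config)
  got <- weightManifest(w)
  ok <- identical(names(exp), names(got)) &&
    all(mapply(function(a, b) identical(as.integer(a), as.integer(b)), exp, got))
  if (!ok)
    fsStop("weightCompatError",
           "weight manifest does not match the model configuration")
  invisible(TRUE)
}

#' Train a model locally for a fixed number of minibatch steps
#'
#' Runs `steps` Adam updates (one minibatch gradient update per step) of the
#' U-Net starting from `start` on the given cases. The whole loop is a pure
#' function of its arguments: minibatch sampling is driven by `seed` through
#' an isolated RNG stream, and the result is bit-reproducible. Optimizer
#' state (Adam moments) is local to the call, i.e. reset at every federated
#' iteration.
#'
#' @param start Starting [WeightSet-class]; its manifest must match `config`.
#' @param train_cases Non-empty list of [PhantomCase-class] (if `steps > 0`).
#' @param config A [ModelConfig-class].
#' @param steps Number of minibatch updates (>= 0). `steps = 0` returns the
#'   start weights unchanged with a missing (`NA`) loss.
#' @param seed Integer seed for minibatch sampling.
#' @return List with `weights` (a [WeightSet-class] carrying
#'   `n_train_samples = length(train_cases)`), `mean_train_loss` (mean loss
#'   over all steps, `NA` if `steps = 0`) and `step_losses` (per-step losses).
#' @export
trainLocal <- function(start, train_cases, config, steps, seed) {
  validObject(config)
  checkManifestAgainstConfig(start, config)
  if (!isCount(steps, min = 0L)) fsStop("configError", "steps must be an integer >= 0")
  n <- length(train_cases)
  if (steps == 0L) {
    w <- updateWeightMeta(start, n_train_samples = n)
    return(list(weights = w, mean_train_loss = NA_real_, step_losses = numeric()))
  }
  if (n == 0L) fsStop("dataError", "cannot train: no training cases supplied")
  H <- config@input_shape[1]; W <- config@input_shape[2]
  for (case in train_cases)
    if (!identical(dim(case@image), c(H, W)))
      fsStop("dataError", sprintf("case %s has shape %s, expected %dx%d",
                                  patientId(case), paste(dim(case@image), collapse = "x"), H, W))
  B <- config@batch_size
  npix <- H * W
  xs <- lapply(train_cases, function(case) as.vector(case@image) / PHANTOM_NORM)
  gsv <- lapply(train_cases, function(case) as.numeric(as.vector(case@mask)))

  params <- paramsFromValues(start@values)
  layers <- names(params)
  mState <- lapply(params, function(pl) list(W = pl$W * 0, b = pl$b * 0))
  vState <- mState
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config@learning_rate
  stepLosses <- numeric(steps)

  withSeed(deriveSeed(seed, 5L), {
    for (step in seq_len(steps)) {
      idx <- sample.int(n, B, replace = TRUE)
      X <- matrix(unlist(xs[idx], use.names = FALSE), ncol = 1L)
      g <- unlist(gsv[idx], use.names = FALSE)
      fw <- unetForward(params, X, H, W, B, config@depth, keepCache = TRUE)
      lg <- lossAndGradZ(fw$z, fw$p, g, config@loss_name)
      stepLosses[step] <- lg$loss
      grads <- unetBackward(params, fw, matrix(lg$dz, ncol = 1L),
                            config@depth, config@base_filters)
      corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
      for (l in layers) {
        for (part in c("W", "b")) {
          gr <- grads[[l]][[part]]
          mState[[l]][[part]] <- b1 * mState[[l]][[part]] + (1 - b1) * gr
          vState[[l]][[part]] <- b2 * vState[[l]][[part]] + (1 - b2) * gr^2
          mHat <- mState[[l]][[part]] / corr1
          vHat <- vState[[l]][[part]] / corr2
          params[[l]][[part]] <- params[[l]][[part]] - lr * mHat / (sqrt(vHat) + eps)
        }
      }
    }
  })

  values <- valuesFromParams(params, names(start@values))
  w <- weightSet(values, task_id = start@meta$task_id,
                 iteration = start@meta$iteration, origin = start@meta$origin,
                 n_train_samples = n)
  list(weights = w, mean_train_loss = mean(stepLosses), step_losses = stepLosses)
}

#' Predict a binary mask for one image
#'
#' Runs the U-Net forward pass (architecture inferred from the weight
#' manifest) and thresholds the per-pixel probability map.
#'
#' @param weights A [WeightSet-class] of U-Net parameters.
#' @param image Numeric matrix; each dimension must be divisible by
#'   `2^depth`.
#' @param threshold Probability threshold in (0, 1); a pixel is foreground if
#'   its probability is at least the threshold. Default 0.5.
#' @return Integer 0/1 matrix of the same shape.
#' @export
predictMask <- function(weights, image, threshold = 0.5) {
  arch <- archFromValues(weights@values)
  d <- dim(image)
  if (is.null(d) || length(d) != 2L)
    fsStop("dataError", "image must be a 2D matrix")
  if (any(d %% 2L^arch$depth != 0L))
    fsStop("dataError", sprintf("image shape %s not divisible by 2^depth = %d",
                                paste(d, collapse = "x"), 2L^arch$depth))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    fsStop("configError", "threshold must lie in (0, 1)")
  params <- paramsFromValues(weights@values)
  X <- matrix(as.vector(image) / PHANTOM_NORM, ncol = 1L)
  fw <- unetForward(params, X, d[1], d[2], 1L, arch$depth, keepCache = FALSE)
  out <- matrix(0L, d[1], d[2])
  out[fw$p >= threshold] <- 1L
  out
}

#' Per-pixel probability map for one image
#'
#' @inheritParams predictMask
#' @return Numeric matrix of probabilities in (0, 1).
#' @export
predictProbabilities <- function(weights, image) {
  arch <- archFromValues(weights@values)
  d <- dim(image)
  params <- paramsFromValues(weights@values)
  X <- matrix(as.vector(image) / PHANTOM_NORM, ncol = 1L)
  fw <- unetForward(params, X, d[1], d[2], 1L, arch$depth, keepCache = FALSE)
  matrix(fw$p, d[1], d[2])
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)` in `[0, 1]`. Two empty masks score 1.0 (a
#' correct rejection: the model correctly predicted the absence of tumor).
#'
#' @param pred,truth Binary (0/1) matrices of identical shape.
#' @return Numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
#' diceScore(a, a)  # 1
diceScore <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    fsStop("dataError", "mask shapes differ")
  pv <- as.vector(pred); tv <- as.vector(truth)
  if (!all(pv %in% c(0, 1)) || !all(tv %in% c(0, 1)))
    fsStop("dataError", "masks must be binary (0/1)")
  sa <- sum(pv); sb <- sum(tv)
  if (sa + sb == 0) return(1)
  2 * sum(pv * tv) / (sa + sb)
}
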