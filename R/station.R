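## The data-station worker: loads its local NIfTI partition, pulls work,
## fetches the previous global model from the aggregation server, evaluates
## it on local validation data, trains locally, and submits weights with its
## iteration token. Raw images and masks never leave the process; the only
## outbound payloads are weight containers and JSON-style control records.

#' Per-iteration training metrics of one station
#'
#' `val_dice_global` is the Dice of the incoming averaged model (aggregated
#' at the previous iteration) on local validation data, measured before
#' local training begins; `val_dice_local` is the Dice of the freshly
#' trained local model on the same data.
#'
#' @slot station_id Reporting station.
#' @slot iteration 0-based federated iteration.
#' @slot steps_run Minibatch updates executed.
#' @slot mean_train_loss Mean training loss over the steps (NA if none).
#' @slot val_dice_global Dice of the incoming global model in `[0, 1]`.
#' @slot val_dice_local Dice of the freshly trained local model in `[0, 1]`.
#' @export
setClass("TrainMetrics", representation(
  station_id = "character", iteration = "integer", steps_run = "integer",
  mean_train_loss = "numeric", val_dice_global = "numeric",
  val_dice_local = "numeric"
))

setValidity("TrainMetrics", function(object) {
  msg <- character()
  if (!isCount(object@steps_run, min = 0L)) msg <- c(msg, "steps_run must be >= 0")
  for (f in c("val_dice_global", "val_dice_local")) {
    v <- slot(object, f)
    if (length(v) != 1L || (!is.na(v) && (v < 0 || v > 1)))
      msg <- c(msg, sprintf("%s must be in [0, 1] or NA", f))
  }
  if (length(msg)) msg else TRUE
})

trainMetrics <- function(station_id, iteration, steps_run, mean_train_loss,
                         val_dice_global, val_dice_local) {
  new("TrainMetrics", station_id = as.character(station_id),
      iteration = as.integer(iteration), steps_run = as.integer(steps_run),
      mean_train_loss = as.numeric(mean_train_loss),
      val_dice_global = as.numeric(val_dice_global),
      val_dice_local = as.numeric(val_dice_local))
}

setMethod("show", "TrainMetrics", function(object) {
  cat(sprintf("TrainMetrics %s it %d: %d steps, loss %.4f, dice global %.3f / local %.3f\n",
              object@station_id, object@iteration, object@steps_run,
              object@mean_train_loss, object@val_dice_global, object@val_dice_local))
})

#' Station runtime configuration
#'
#' @slot station_id Entity id of the station.
#' @slot data_root Directory containing `train/` and `validation/` NIfTI
#'   folders (empty string when cases are provided in memory).
#' @slot model_config The [ModelConfig-class] of the task.
#' @slot steps_per_iteration Default minibatch updates per federated
#'   iteration (a task's `input_params$steps_per_iteration` overrides it).
#' @slot deterministic Reproducible-training flag (single RNG stream,
#'   seeded minibatch sampling; the package backend is deterministic by
#'   construction).
#' @slot seed Station base seed; per-iteration seeds derive from it via
#'   [iterationSeed()].
#' @slot threshold Probability threshold for validation Dice.
#' @export
setClass("StationConfig", representation(
  station_id = "character", data_root = "character", model_config = "ModelConfig",
  steps_per_iteration = "integer", deterministic = "logical", seed = "integer",
  threshold = "numeric"
))

setValidity("StationConfig", function(object) {
  msg <- character()
  if (!isScalarString(object@station_id)) msg <- c(msg, "station_id must be a non-empty string")
  if (!isCount(object@steps_per_iteration)) msg <- c(msg, "steps_per_iteration must be >= 1")
  if (object@threshold <= 0 || object@threshold >= 1) msg <- c(msg, "threshold must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a StationConfig
#'
#' @param station_id Station entity id.
#' @param model_config A [ModelConfig-class] (default [modelConfig()]).
#' @param data_root NIfTI data directory with `train/` and `validation/`
#'   (default `""`: cases supplied in memory).
#' @param steps_per_iteration Default steps per iteration (default 50).
#' @param deterministic Reproducibility flag (default TRUE).
#' @param seed Station base seed (default 0).
#' @param threshold Dice threshold (default 0.5).
#' @return A [StationConfig-class].
#' @export
stationConfig <- function(station_id, model_config = modelConfig(),
                          data_root = "", steps_per_iteration = 50,
                          deterministic = TRUE, seed = 0, threshold = 0.5) {
  new("StationConfig", station_id = as.character(station_id),
      data_root = as.character(data_root), model_config = model_config,
      steps_per_iteration = as.integer(steps_per_iteration),
      deterministic = as.logical(deterministic), seed = as.integer(seed),
      threshold = as.numeric(threshold))
}

#' Load and validate a station's local NIfTI partition
#'
#' Scans `data_root/train` and `data_root/validation` for
#' `<patient>_img.nii.gz` / `<patient>_msk.nii.gz` pairs. A missing mask, a
#' malformed file, or an empty folder aborts startup: a station cannot join
#' a federation without both a training and a validation sample.
#'
#' @param config A [StationConfig-class] with a non-empty `data_root`.
#' @return List with `train` and `validation` lists of [PhantomCase-class].
#' @export
loadLocalPartition <- function(config) {
  root <- config@data_root
  if (!nzchar(root) || !dir.exists(root))
    fsStop("startupError", sprintf("data_root '%s' does not exist", root))
  out <- list()
  for (subset in c("train", "validation")) {
    dirp <- file.path(root, subset)
    if (!dir.exists(dirp))
      fsStop("startupError", sprintf("missing %s folder under %s", subset, root))
    imgs <- sort(list.files(dirp, pattern = "_img\\.nii(\\.gz)?$", full.names = TRUE))
    if (!length(imgs))
      fsStop("startupError", sprintf(
        "station %s: %s folder is empty; local %s data is required",
        config@station_id, subset, subset))
    cases <- lapply(imgs, function(ip) {
      mp <- sub("_img\\.nii", "_msk.nii", ip)
      pid <- sub("_img\\.nii(\\.gz)?$", "", basename(ip))
      if (!file.exists(mp))
        fsStop("startupError", sprintf("patient %s: mask file missing", pid))
      tryCatch(readCaseNifti(ip, mp),
               fedsegError = function(e) fsStop("startupError", sprintf(
                 "patient %s: %s", pid, conditionMessage(e))))
    })
    out[[subset]] <- cases
  }
  out
}

#' Mean Dice of a model over a validation set
#'
#' Evaluates `weights` on every validation case and averages the per-case
#' Dice scores. `predictFun` is injectable so tests can substitute an oracle
#' or degenerate predictor.
#'
#' @param weights A [WeightSet-class].
#' @param val_cases Non-empty list of [PhantomCase-class].
#' @param threshold Probability threshold (default 0.5).
#' @param predictFun Function `(weights, image, threshold)` returning a
#'   binary mask; default [predictMask()].
#' @return Mean Dice in `[0, 1]`.
#' @export
evaluateGlobalOnValidation <- function(weights, val_cases, threshold = 0.5,
                                       predictFun = predictMask) {
  if (!length(val_cases)) fsStop("dataError", "validation set is empty")
  mean(vapply(val_cases, function(case)
    diceScore(predictFun(weights, case@image, threshold), case@mask), 0))
}

## Retry helper for transport calls: transient unavailability is retried
## with exponential backoff, everything else propagates immediately. The
## expression is re-evaluated afresh on every attempt.
withRetries <- function(expr, attempts = 3L, waitBase = 0.05) {
  q <- substitute(expr)
  env <- parent.frame()
  for (k in seq_len(attempts)) {
    res <- tryCatch(eval(q, env), transportUnavailable = function(e) e)
    if (!inherits(res, "transportUnavailable")) return(res)
    if (k < attempts) Sys.sleep(waitBase * 2^(k - 1L))
  }
  stop(res)
}

#' Run one station training cycle
#'
#' The station protocol for one federated iteration:
#' (1) fetch the previous iteration's averaged model from the aggregation
#' server (bearer token required), (2) evaluate it on the local validation
#' sample (`val_dice_global`), (3) train locally for the configured number
#' of steps, (4) evaluate the fresh local model (`val_dice_local`),
#' (5) submit the local weights to the aggregation server under the same
#' token, and (6) report status and metrics to the coordinator. Aggregation
#'-server outages are retried (3 attempts, exponential backoff); a final
#' failure or token rejection files an abort report before propagating.
#'
#' @param config A [StationConfig-class].
#' @param task The [TaskSpec-class] being executed.
#' @param iteration 0-based iteration index.
#' @param token This station's iteration token.
#' @param transport The [InMemoryTransport] connecting the federation.
#' @param session Coordinator session of this station.
#' @param train_cases,val_cases Local cases; loaded from `config@data_root`
#'   when omitted.
#' @param aggregator_endpoint,coordinator_endpoint Endpoint names (defaults
#'   `"SAS"`, `"coordinator"`).
#' @return List with `ack` (submission acknowledgement) and `metrics`
#'   (a [TrainMetrics-class]).
#' @export
runTrainingCycle <- function(config, task, iteration, token, transport, session,
                             train_cases = NULL, val_cases = NULL,
                             aggregator_endpoint = "SAS",
                             coordinator_endpoint = "coordinator") {
  if (is.null(train_cases) || is.null(val_cases)) {
    part <- loadLocalPartition(config)
    train_cases <- part$train; val_cases <- part$validation
  }
  sid <- config@station_id
  steps <- task@input_params$steps_per_iteration
  if (is.null(steps)) steps <- config@steps_per_iteration
  reportAbort <- function(err) {
    try(transport$request(sid, coordinator_endpoint, "report-status", list(
      session = session, task_id = task@task_id, iteration = iteration,
      state = "aborted")), silent = TRUE)
    stop(err)
  }
  global <- tryCatch(
    withRetries(transport$request(sid, aggregator_endpoint, "get-global-model",
                                  list(token = token))),
    fedsegError = reportAbort)
  valDiceGlobal <- evaluateGlobalOnValidation(global, val_cases, config@threshold)
  tr <- trainLocal(global, train_cases, config@model_config, steps,
                   seed = iterationSeed(config@seed, iteration))
  w <- updateWeightMeta(tr$weights, task_id = task@task_id,
                        iteration = iteration, origin = sid)
  valDiceLocal <- evaluateGlobalOnValidation(w, val_cases, config@threshold)
  ack <- tryCatch(
    withRetries(transport$request(sid, aggregator_endpoint, "submit-model",
                                  list(token = token, weights = w))),
    fedsegError = reportAbort)
  metrics <- trainMetrics(sid, iteration, length(tr$step_losses),
                          tr$mean_train_loss, valDiceGlobal, valDiceLocal)
  transport$request(sid, coordinator_endpoint, "report-status", list(
    session = session, task_id = task@task_id, iteration = iteration,
    state = "completed", metrics = metrics))
  list(ack = ack, metrics = metrics)
}
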