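## The secure aggregation server (SAS): a data-free intermediary that runs
## the master algorithm. It creates and broadcasts the common initial model,
## holds the synchronous barrier (no averaging until every rostered station
## has submitted), performs FedAvg, keeps every intermediate model
## inaccessible to anything but a token-bearing station, survives station
## dropouts by re-opening the iteration from the latest successful model,
## and hands exactly one final model to the coordinator.

#' Federated averaging of model weights
#'
#' Parameter-wise convex combination of one or more WeightSets sharing a
#' manifest: `w = sum_k (n_k / n) w_k` with `n_k` the per-station training
#' sample counts (`sample_weighted`, the standard FedAvg weighting) or
#' `n_k = 1` (`uniform`).
#'
#' @param models Non-empty list of [WeightSet-class] with identical manifests.
#' @param weighting `"sample_weighted"` (default) or `"uniform"`.
#' @return A [WeightSet-class] with `origin = "SAS"` and `n_train_samples`
#'   equal to the pooled sample count.
#' @export
#' @examples
#' a <- weightSet(list(w = c(1, 3)), n_train_samples = 1)
#' b <- weightSet(list(w = c(3, 5)), n_train_samples = 3)
#' weightValues(fedavgAggregate(list(a, b), "uniform"))$w        # 2 4
#' weightValues(fedavgAggregate(list(a, b), "sample_weighted"))$w
fedavgAggregate <- function(models, weighting = c("sample_weighted", "uniform")) {
  weighting <- match.arg(weighting)
  if (!length(models)) fsStop("aggregationError", "no models to aggregate")
  ref <- models[[1]]
  for (m in models[-1])
    if (!manifestsMatch(ref, m))
      fsStop("manifestMismatch", "models do not share one weight manifest")
  n <- vapply(models, function(m) as.numeric(m@meta$n_train_samples), 0)
  if (weighting == "sample_weighted") {
    if (sum(n) <= 0)
      fsStop("aggregationError", "sample_weighted averaging requires positive sample counts")
    alpha <- n / sum(n)
  } else {
    alpha <- rep(1 / length(models), length(models))
  }
  values <- ref@values
  for (nm in names(values)) {
    acc <- alpha[1] * models[[1]]@values[[nm]]
    for (k in seq_along(models)[-1]) acc <- acc + alpha[k] * models[[k]]@values[[nm]]
    values[[nm]] <- acc
  }
  weightSet(values, task_id = ref@meta$task_id, iteration = ref@meta$iteration,
            origin = "SAS", n_train_samples = as.integer(sum(n)))
}

#' Secure aggregation server
#'
#' Reference-semantics server object; see the package vignette for the full
#' protocol. All station-facing methods demand a valid current-iteration
#' token and refuse everything else without touching state.
#'
#' @field task_id Active task id (empty until a task starts).
#' @field expected_stations Station roster.
#' @field n_iterations Configured iteration count.
#' @field current_iteration 0-based iteration now accepting submissions.
#' @field received Accepted submissions of the open iteration, by station.
#' @field latest_model The latest successful aggregated model (iteration 0:
#'   the common initial model); never rolled back.
#' @field status `"idle"`, `"waiting"`, `"finished"` or `"aborted"`.
#' @field signing_key Per-task HMAC key shared with the coordinator.
#' @field weighting FedAvg weighting mode.
#' @field tokens Current-iteration tokens by station.
#' @field events Aggregation/abort/finalize event records.
#' @field token_lifetime Token lifetime in seconds.
#' @export SecureAggregator
#' @exportClass SecureAggregator
SecureAggregator <- setRefClass("SecureAggregator",
  fields = list(
    task_id = "character", expected_stations = "character",
    n_iterations = "integer", current_iteration = "integer",
    received = "list", latest_model = "ANY", status = "character",
    signing_key = "ANY", weighting = "character", tokens = "list",
    events = "list", token_lifetime = "numeric"
  ),
  methods = list(
    initialize = function(...) {
      task_id <<- ""; expected_stations <<- character()
      n_iterations <<- 0L; current_iteration <<- 0L
      received <<- list(); latest_model <<- NULL; status <<- "idle"
      signing_key <<- NULL; weighting <<- "sample_weighted"
      tokens <<- list(); events <<- list(); token_lifetime <<- 7200
      callSuper(...)
    },

    startTask = function(task, model_config, signingKey,
                         now = as.numeric(Sys.time())) {
      "Accept the master task: initialize iteration-0 state, create the
       common initial model from the task's model seed, and mint
       iteration-0 tokens."
      if (status %in% c("waiting", "aggregating"))
        fsStop("conflictError", sprintf("task '%s' is already active", task_id))
      validObject(task)
      if (!length(task@station_ids)) fsStop("configError", "station roster is empty")
      task_id <<- task@task_id
      expected_stations <<- task@station_ids
      n_iterations <<- task@n_iterations
      current_iteration <<- 0L
      received <<- list()
      signing_key <<- signingKey
      w <- task@input_params$weighting
      weighting <<- if (is.null(w)) "sample_weighted" else match.arg(w, c("sample_weighted", "uniform"))
      seed <- task@input_params$model_seed
      if (is.null(seed)) fsStop("configError", "task input_params must carry model_seed")
      latest_model <<- initWeights(model_config, seed, task_id = task@task_id)
      status <<- "waiting"
      openIteration(now)
      invisible(.self)
    },

    openIteration = function(now = as.numeric(Sys.time())) {
      "Mint fresh per-station tokens for the current iteration."
      tokens <<- stats::setNames(lapply(expected_stations, function(s)
        issueIterationToken(tokenClaims(s, task_id, current_iteration,
                                        issued_at = now,
                                        lifetime = token_lifetime),
                            signing_key)), expected_stations)
      invisible(tokens)
    },

    currentTokens = function() tokens,

    validateToken = function(token, now = as.numeric(Sys.time())) {
      claims <- validateIterationToken(token, signing_key, task_id,
                                       current_iteration, expected_stations,
                                       now = now)
      ## tokens are rotated when an iteration opens or re-opens after an
      ## abort; a superseded token is a replay even if its claims still match
      if (!token %in% unlist(tokens, use.names = FALSE))
        tokenRejection("tokenReplay", "token has been superseded by a fresh issue")
      claims
    },

    releaseGlobalModel = function(token, now = as.numeric(Sys.time())) {
      "Serve the latest successful model (read-only) to a station holding a
       valid current-iteration token."
      validateToken(token, now)
      if (is.null(latest_model))
        fsStop("retryLater", "no aggregated model is available yet; retry later")
      latest_model
    },

    acceptModelSubmission = function(token, weights, now = as.numeric(Sys.time())) {
      "Barrier ingest: validate the token, refuse manifest mismatches and
       duplicates, and trigger FedAvg exactly once when the roster is
       complete."
      claims <- validateToken(token, now)          # any rejection: state untouched
      if (!is(weights, "WeightSet"))
        fsStop("formatError", "submission payload is not a WeightSet")
      if (!manifestsMatch(latest_model, weights))
        fsStop("manifestMismatch", "submitted weights do not match the task manifest")
      sid <- claims@station_id
      if (sid %in% names(received))
        fsStop("duplicateSubmission", sprintf(
          "station %s already submitted for iteration %d (first submission wins)",
          sid, current_iteration))
      received[[sid]] <<- weights
      if (length(received) < length(expected_stations))
        return(list(status = "waiting",
                    received = length(received),
                    expected = length(expected_stations)))
      aggregateNow(now)
      list(status = if (status == "finished") "finished" else "aggregated",
           received = 0L, expected = length(expected_stations))
    },

    aggregateNow = function(now = as.numeric(Sys.time())) {
      status <<- "aggregating"
      agg <- fedavgAggregate(unname(received[expected_stations]), weighting)
      agg <- updateWeightMeta(agg, task_id = task_id,
                              iteration = current_iteration, origin = "SAS")
      latest_model <<- agg
      events[[length(events) + 1L]] <<- list(
        iteration = current_iteration, event = "aggregate",
        stations = names(received), time = now)
      received <<- list()
      current_iteration <<- current_iteration + 1L
      if (current_iteration >= n_iterations) {
        status <<- "finished"
        tokens <<- list()
      } else {
        status <<- "waiting"
        openIteration(now)
      }
      invisible(NULL)
    },

    reportDropout = function(failed_station, now = as.numeric(Sys.time())) {
      "Dropout policy (abort_iteration): discard the open iteration's
       partial submissions and re-open the same iteration with fresh
       tokens; the latest successful model is never rolled back."
      if (!failed_station %in% expected_stations)
        fsStop("notFoundError", sprintf("unknown station '%s'", failed_station))
      if (status == "finished")
        fsStop("conflictError", "task already finished")
      events[[length(events) + 1L]] <<- list(
        iteration = current_iteration, event = "abort",
        stations = failed_station, time = now)
      received <<- list()
      status <<- "waiting"
      openIteration(now)
      invisible(.self)
    },

    finalizeTask = function() {
      "Release the final aggregated model for coordinator storage; refused
       until the configured iteration count is reached. Intermediates are
       never released on this or any other coordinator/researcher path."
      if (status != "finished")
        fsStop("prematureFinalize", sprintf(
          "task is at iteration %d of %d; finalize refused",
          current_iteration, n_iterations))
      events[[length(events) + 1L]] <<- list(
        iteration = n_iterations - 1L, event = "finalize",
        stations = character(), time = as.numeric(Sys.time()))
      latest_model
    },

    show = function() {
      cat(sprintf("SecureAggregator: task '%s', status %s, iteration %d/%d, %d/%d submissions held\n",
                  task_id, status, current_iteration, n_iterations,
                  length(received), length(expected_stations)))
    }
  )
)
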