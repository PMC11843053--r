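## Desk-scale federation driver: wires a coordinator, a secure aggregation
## server and K stations over the in-memory transport and runs the full
## task lifecycle end-to-end — registration, authentication, task
## submission, pull-based distribution, the per-iteration token/train/
## submit/aggregate loop, optional forced dropouts, finalization and
## researcher download — collecting a per-iteration history equivalent to
## the Dice/loss-per-iteration curves a federation monitor would plot.

#' Per-iteration federation history
#'
#' One record per station training cycle (`local_train`) and one per
#' aggregation-server event (`aggregate`, `abort`, `finalize`).
#'
#' @slot records data.frame with columns `iteration`, `actor`, `event`,
#'   `mean_train_loss`, `val_dice_global`, `val_dice_local`, `wall_time`.
#' @export
setClass("FederationHistory", representation(records = "data.frame"))

setValidity("FederationHistory", function(object) {
  need <- c("iteration", "actor", "event", "mean_train_loss",
            "val_dice_global", "val_dice_local", "wall_time")
  if (!all(need %in% names(object@records)))
    return(sprintf("records must have columns: %s", paste(need, collapse = ", ")))
  TRUE
})

#' @export
setGeneric("historyRecords", function(x) standardGeneric("historyRecords"))
#' @describeIn FederationHistory-class The records data.frame.
#' @param x A `FederationHistory`.
#' @export
setMethod("historyRecords", "FederationHistory", function(x) x@records)

setMethod("show", "FederationHistory", function(object) {
  r <- object@records
  agg <- r[r$event == "aggregate", , drop = FALSE]
  cat(sprintf("FederationHistory: %d records, %d completed iterations\n",
              nrow(r), nrow(agg)))
  lt <- r[r$event == "local_train", , drop = FALSE]
  if (nrow(lt)) {
    per <- tapply(lt$val_dice_global, lt$iteration, mean)
    cat("  mean val_dice_global per iteration:",
        paste(sprintf("%.3f", per), collapse = " "), "\n")
  }
})

CONFIG_DEFAULTS <- list(
  split_fraction = 0.8,
  n_iterations = 3L,
  steps_per_iteration = 50L,
  weighting = "sample_weighted",
  threshold = 0.5,
  deterministic = TRUE,
  seed = 1L,
  station_seeds = NULL,
  task_id = "task-001",
  data_root = NULL,
  ports = list(api_forwarder = 5050L, algorithm_api = 7000L)
)

MODEL_DEFAULTS <- list(depth = 2L, base_filters = 8L, input_shape = c(64L, 64L),
                       learning_rate = 5e-4, batch_size = 2L,
                       loss_name = "bce_dice")

#' Load and validate a federation run configuration
#'
#' Reads a YAML or JSON run configuration, rejects unknown keys by name,
#' applies defaults (threshold 0.5, sample-weighted FedAvg, deterministic
#' mode on, ...) and returns the fully resolved configuration. `sites`
#' entries use the [siteProfile()] fields; `model` uses the [modelConfig()]
#' fields. The `ports` block records the deployment defaults of the two-level
#' aggregation-server API (forwarder 5050, algorithm API 7000); the
#' in-memory transport implements the same contract without sockets.
#'
#' @param path Configuration file (`.yaml`/`.yml`/`.json`).
#' @param quiet Suppress the resolved-config echo? Default TRUE.
#' @return Validated configuration list.
#' @export
loadConfig <- function(path, quiet = TRUE) {
  if (!file.exists(path)) fsStop("ioError", sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  resolveConfig(raw, quiet = quiet)
}

#' Resolve and validate a configuration list
#'
#' @param config Named list as in [loadConfig()].
#' @param quiet Suppress the resolved-config echo? Default TRUE.
#' @return Validated configuration list with all defaults filled.
#' @export
resolveConfig <- function(config, quiet = TRUE) {
  known <- c("sites", "model", names(CONFIG_DEFAULTS))
  bad <- setdiff(names(config), known)
  if (length(bad))
    fsStop("schemaError", sprintf("unknown configuration keys: %s",
                                  paste(bad, collapse = ", ")))
  out <- modifyList(CONFIG_DEFAULTS, config[setdiff(names(config), c("sites", "model"))],
                    keep.null = TRUE)
  modelIn <- if (is.null(config$model)) list() else config$model
  badm <- setdiff(names(modelIn), names(MODEL_DEFAULTS))
  if (length(badm))
    fsStop("schemaError", sprintf("unknown model keys: %s", paste(badm, collapse = ", ")))
  out$model <- modifyList(MODEL_DEFAULTS, modelIn)
  if (!isCount(out$n_iterations))
    fsStop("validationError", "n_iterations must be an integer >= 1")
  if (!isCount(out$steps_per_iteration, min = 0L))
    fsStop("validationError", "steps_per_iteration must be an integer >= 0")
  if (!is.numeric(out$split_fraction) || out$split_fraction <= 0 || out$split_fraction >= 1)
    fsStop("validationError", "split_fraction must lie in (0, 1)")
  if (!out$weighting %in% c("sample_weighted", "uniform"))
    fsStop("validationError", "weighting must be sample_weighted or uniform")
  if (out$threshold <= 0 || out$threshold >= 1)
    fsStop("validationError", "threshold must lie in (0, 1)")
  if (is.null(config$sites)) {
    out$sites <- defaultSiteProfiles(seed = out$seed)
  } else if (all(vapply(config$sites, is, TRUE, "SiteProfile"))) {
    out$sites <- config$sites
  } else {
    out$sites <- lapply(config$sites, function(entry) do.call(siteProfile, entry))
  }
  mc <- out$model
  out$model_config <- modelConfig(mc$depth, mc$base_filters, mc$input_shape,
                                  mc$learning_rate, mc$batch_size, mc$loss_name)
  if (!quiet) {
    echo <- out; echo$sites <- sprintf("<%d site profiles>", length(out$sites))
    echo$model_config <- NULL
    message("resolved configuration: ",
            jsonlite::toJSON(echo, auto_unbox = TRUE, null = "null"))
  }
  out
}

#' Simulate a complete federation in one process
#'
#' Runs the full task lifecycle over the in-memory transport: entity
#' registration and authentication, researcher task submission, pull-based
#' master/subtask distribution, the synchronous per-iteration loop (token
#' issue, global-model fetch, local training, validation evaluation,
#' submission, FedAvg at the barrier), optional forced dropout with
#' recovery from the latest successful model, finalization, and the
#' researcher's final download. Deterministic: identical configurations
#' yield identical final weights and history (wall times aside).
#'
#' @param config Configuration list from [loadConfig()]/[resolveConfig()],
#'   or a raw list (resolved on the fly).
#' @param failAt Optional `list(station =, iteration =)`: force that station
#'   to abort once at that iteration, exercising dropout recovery.
#' @param onIteration Optional callback `function(iteration, coordinator,
#'   aggregator, transport)` invoked after each completed aggregation.
#' @param keepModels Keep a copy of each iteration's aggregated model in the
#'   result (driver-side only, never transmitted; default FALSE).
#' @return List with `final_model` ([WeightSet-class]), `history`
#'   ([FederationHistory-class]), `coordinator`, `aggregator`, `transport`,
#'   `cohort`, `config`, and `iteration_models` (if requested).
#' @export
simulateFederation <- function(config, failAt = NULL, onIteration = NULL,
                               keepModels = FALSE) {
  if (is.null(config$model_config)) config <- resolveConfig(config)
  profiles <- config$sites
  stationIds <- vapply(profiles, function(p) p@site_id, "")
  cohort <- generatePartitionedCohort(profiles, config$split_fraction)

  useDisk <- !is.null(config$data_root) && nzchar(config$data_root)
  if (useDisk) writeCohortNifti(cohort, config$data_root, force = TRUE)

  transport <- InMemoryTransport$new()
  coordinator <- Coordinator$new()
  sas <- SecureAggregator$new()

  ## task lifecycle step 1: every entity authenticates with the coordinator
  pw <- function(id) paste0("pw-", id)
  coordinator$registerEntity("researcher", "researcher", pw("researcher"))
  coordinator$registerEntity("sas", "aggregator", pw("sas"))
  for (s in stationIds) coordinator$registerEntity(s, "station", pw(s))
  researcherSession <- coordinator$authenticate("researcher", pw("researcher"))
  sasSession <- coordinator$authenticate("sas", pw("sas"))
  stationSessions <- stats::setNames(
    lapply(stationIds, function(s) coordinator$authenticate(s, pw(s))), stationIds)

  transport$register("coordinator", function(route, payload, from) {
    switch(route,
      "report-status" = coordinator$reportStatus(payload$session, payload$task_id,
                                                 payload$iteration, payload$state,
                                                 payload$metrics),
      "reopen-iteration" = coordinator$reopenIteration(payload$session, payload$task_id,
                                                       payload$iteration),
      "store-final-model" = coordinator$storeFinalModel(payload$session,
                                                        payload$task_id, payload$weights),
      fsStop("notFoundError", sprintf("unknown coordinator route '%s'", route)))
  })
  transport$register("SAS", function(route, payload, from) {
    switch(route,
      "get-global-model" = sas$releaseGlobalModel(payload$token),
      "submit-model" = sas$acceptModelSubmission(payload$token, payload$weights),
      "report-dropout" = sas$reportDropout(payload$station),
      fsStop("notFoundError", sprintf("unknown aggregator route '%s'", route)))
  })

  ## researcher submits the task; the aggregator is first to receive it
  task <- taskSpec(config$task_id, stationIds, config$n_iterations,
                   aggregator_id = "sas",
                   input_params = list(model_seed = config$seed,
                                       steps_per_iteration = config$steps_per_iteration,
                                       weighting = config$weighting))
  coordinator$submitTask(researcherSession, task)
  master <- Filter(function(it) it$type == "master", coordinator$pullWork(sasSession))[[1]]
  sas$startTask(master$task, config$model_config, master$signing_key)

  stationSeedFor <- function(s) {
    idx <- match(s, stationIds)
    if (!is.null(config$station_seeds)) return(as.integer(config$station_seeds[[idx]]))
    if (!config$deterministic) return(sample.int(2147483646L, 1L))
    deriveSeed(config$seed, 23L, idx)
  }
  stationConfigs <- stats::setNames(lapply(profiles, function(p) {
    stationConfig(p@site_id, model_config = config$model_config,
                  data_root = if (useDisk) file.path(config$data_root,
                                                     paste0("site_", p@site_id)) else "",
                  steps_per_iteration = config$steps_per_iteration,
                  deterministic = config$deterministic,
                  seed = stationSeedFor(p@site_id),
                  threshold = config$threshold)
  }), stationIds)

  localData <- stats::setNames(lapply(stationIds, function(s) {
    if (useDisk) loadLocalPartition(stationConfigs[[s]])
    else list(train = siteCases(cohort, s, "train"),
              validation = siteCases(cohort, s, "validation"))
  }), stationIds)

  for (s in stationIds) {
    sub <- Filter(function(it) it$type == "subtask", coordinator$pullWork(stationSessions[[s]]))
    if (!length(sub)) fsStop("startupError", sprintf("no subtask queued for station %s", s))
  }

  histLocal <- list()
  iterationModels <- list()
  failPending <- !is.null(failAt)

  while (sas$status != "finished") {
    it <- sas$current_iteration
    toks <- sas$currentTokens()
    aborted <- FALSE
    for (s in stationIds) {
      if (failPending && identical(failAt$station, s) &&
          identical(as.integer(failAt$iteration), it)) {
        ## forced dropout: the station files an abort report; the SAS
        ## discards partial submissions and re-opens the iteration, whose
        ## partial local_train records are superseded by the re-run
        failPending <- FALSE
        transport$request(s, "coordinator", "report-status", list(
          session = stationSessions[[s]], task_id = task@task_id,
          iteration = it, state = "aborted"))
        transport$request(s, "SAS", "report-dropout", list(station = s))
        transport$request("sas", "coordinator", "reopen-iteration", list(
          session = sasSession, task_id = task@task_id, iteration = it))
        histLocal <- Filter(function(d) d$iteration != it, histLocal)
        aborted <- TRUE
        break
      }
      t0 <- as.numeric(Sys.time())
      res <- runTrainingCycle(stationConfigs[[s]], task, it, toks[[s]],
                              transport, stationSessions[[s]],
                              train_cases = localData[[s]]$train,
                              val_cases = localData[[s]]$validation)
      m <- res$metrics
      histLocal[[length(histLocal) + 1L]] <- data.frame(
        iteration = it, actor = s, event = "local_train",
        mean_train_loss = m@mean_train_loss,
        val_dice_global = m@val_dice_global,
        val_dice_local = m@val_dice_local,
        wall_time = as.numeric(Sys.time()) - t0)
    }
    if (aborted) next
    if (keepModels) iterationModels[[as.character(it)]] <- sas$latest_model
    if (!is.null(onIteration)) onIteration(it, coordinator, sas, transport)
  }

  finalModel <- sas$finalizeTask()
  transport$request("sas", "coordinator", "store-final-model",
                    list(session = sasSession, task_id = task@task_id,
                         weights = finalModel))
  downloaded <- coordinator$fetchFinalModel(researcherSession, task@task_id)

  sasRecords <- lapply(sas$events, function(ev) data.frame(
    iteration = ev$iteration, actor = "SAS", event = ev$event,
    mean_train_loss = NA_real_, val_dice_global = NA_real_,
    val_dice_local = NA_real_, wall_time = NA_real_))
  records <- do.call(rbind, c(histLocal, sasRecords))
  records <- records[order(records$iteration, records$event != "local_train"), ]
  rownames(records) <- NULL
  history <- new("FederationHistory", records = records)

  out <- list(final_model = downloaded, history = history,
              coordinator = coordinator, aggregator = sas,
              transport = transport, cohort = cohort, config = config,
              station_configs = stationConfigs)
  if (keepModels) out$iteration_models <- iterationModels
  out
}

#' Export a federation history as CSV
#'
#' Writes one row per record in documented column order, plus a
#' per-iteration summary table (`<path stem>-summary.csv`) with the mean
#' training loss and mean validation Dice across stations.
#'
#' @param history A [FederationHistory-class].
#' @param path Output CSV path.
#' @return Invisibly, a character vector of the two written paths.
#' @export
exportHistory <- function(history, path) {
  r <- historyRecords(history)
  if (!nrow(r)) fsStop("dataError", "history is empty")
  cols <- c("iteration", "actor", "event", "mean_train_loss",
            "val_dice_global", "val_dice_local", "wall_time")
  write.csv(r[, cols], path, row.names = FALSE, quote = FALSE)
  lt <- r[r$event == "local_train", , drop = FALSE]
  summary <- data.frame(
    iteration = sort(unique(lt$iteration)),
    mean_train_loss = as.numeric(tapply(lt$mean_train_loss, lt$iteration, mean)),
    mean_val_dice_global = as.numeric(tapply(lt$val_dice_global, lt$iteration, mean)),
    mean_val_dice_local = as.numeric(tapply(lt$val_dice_local, lt$iteration, mean)))
  spath <- sub("(\\.[Cc][Ss][Vv])?$", "-summary.csv", path)
  if (identical(spath, path)) spath <- paste0(path, "-summary.csv")
  write.csv(summary, spath, row.names = FALSE, quote = FALSE)
  invisible(c(path, spath))
}
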