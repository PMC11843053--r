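## The central coordinating server: entity registry with salted-digest
## credentials, session-based authentication, task metadata storage,
## pull-based work distribution, per-(iteration, station) status
## bookkeeping, and final-model-only persistence. The coordinator never
## relays weights during training: weight traffic flows station <-> SAS
## only, and the one WeightSet it ever stores is the finished global model.

#' Researcher-submitted task description
#'
#' @slot task_id Unique task identifier.
#' @slot algorithm_ref Reference to the training algorithm bundle (the
#'   analogue of a container image name).
#' @slot input_params Key-value list; recognised keys are `model_seed`
#'   (initial-model seed), `steps_per_iteration` and `weighting`.
#' @slot n_iterations Number of federated iterations (>= 1).
#' @slot aggregator_id Registered aggregator entity running the task.
#' @slot station_ids Non-empty roster of registered station entities.
#' @export
setClass("TaskSpec", representation(
  task_id = "character", algorithm_ref = "character", input_params = "list",
  n_iterations = "integer", aggregator_id = "character", station_ids = "character"
))

setValidity("TaskSpec", function(object) {
  msg <- character()
  if (!isScalarString(object@task_id)) msg <- c(msg, "task_id must be a non-empty string")
  if (!isCount(object@n_iterations)) msg <- c(msg, "n_iterations must be an integer >= 1")
  if (!length(object@station_ids) || anyDuplicated(object@station_ids))
    msg <- c(msg, "station_ids must be a non-empty set of unique ids")
  if (!isScalarString(object@aggregator_id)) msg <- c(msg, "aggregator_id must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' Construct a TaskSpec
#'
#' @param task_id Unique task identifier.
#' @param station_ids Roster of station entity ids.
#' @param n_iterations Number of federated iterations (>= 1).
#' @param aggregator_id Aggregator entity id (default `"sas"`).
#' @param algorithm_ref Algorithm bundle reference (default
#'   `"unet-fedavg"`).
#' @param input_params List of algorithm inputs (`model_seed`,
#'   `steps_per_iteration`, `weighting`).
#' @return A [TaskSpec-class].
#' @export
taskSpec <- function(task_id, station_ids, n_iterations, aggregator_id = "sas",
                     algorithm_ref = "unet-fedavg", input_params = list()) {
  new("TaskSpec", task_id = as.character(task_id),
      algorithm_ref = as.character(algorithm_ref),
      input_params = input_params, n_iterations = as.integer(n_iterations),
      aggregator_id = as.character(aggregator_id),
      station_ids = as.character(station_ids))
}

setMethod("show", "TaskSpec", function(object) {
  cat(sprintf("TaskSpec '%s': %d iterations, aggregator %s, %d stations (%s)\n",
              object@task_id, object@n_iterations, object@aggregator_id,
              length(object@station_ids), paste(object@station_ids, collapse = ", ")))
})

## role -> allowed coordinator operations
ROLE_ALLOW <- list(
  researcher = c("submitTask", "taskStatus", "fetchFinalModel"),
  station = c("pullWork", "reportStatus", "taskStatus"),
  aggregator = c("pullWork", "reportStatus", "storeFinalModel",
                 "reopenIteration", "taskStatus")
)

credentialDigest <- function(salt, password) {
  as.raw(openssl::sha256(c(salt, charToRaw(password))))
}

#' Central coordinating server
#'
#' @field entities Registry: entity id -> role, salt, credential digest.
#' @field sessions Active sessions: session id -> entity, role, expiry.
#' @field tasks Task store: metadata, work queue, status matrix, history,
#'   final model (at most one, only after finish).
#' @field session_ttl Session lifetime in seconds.
#' @field lease_ttl Work-item lease timeout in seconds.
#' @field journal_path Optional JSON-lines event journal file.
#' @export Coordinator
#' @exportClass Coordinator
Coordinator <- setRefClass("Coordinator",
  fields = list(entities = "list", sessions = "list", tasks = "list",
                session_ttl = "numeric", lease_ttl = "numeric",
                journal_path = "character"),
  methods = list(
    initialize = function(..., session_ttl = 3600, lease_ttl = 600,
                          journal_path = "") {
      entities <<- list(); sessions <<- list(); tasks <<- list()
      session_ttl <<- session_ttl; lease_ttl <<- lease_ttl
      journal_path <<- journal_path
      callSuper(...)
    },

    journal = function(event, data = list()) {
      if (nzchar(journal_path))
        cat(jsonlite::toJSON(c(list(event = event, time = as.numeric(Sys.time())), data),
                             auto_unbox = TRUE),
            "\n", file = journal_path, append = TRUE)
      invisible(NULL)
    },

    registerEntity = function(entity_id, role, password) {
      "Register a researcher, station or aggregator. Credentials are stored
       as salted SHA-256 digests only."
      if (!isScalarString(entity_id)) fsStop("configError", "entity_id must be a non-empty string")
      role <- match.arg(role, c("researcher", "station", "aggregator"))
      if (!is.null(entities[[entity_id]]))
        fsStop("conflictError", sprintf("entity '%s' is already registered", entity_id))
      salt <- openssl::rand_bytes(16)
      entities[[entity_id]] <<- list(role = role, salt = salt,
                                     digest = credentialDigest(salt, password))
      journal("register", list(entity = entity_id, role = role))
      invisible(list(entity_id = entity_id, role = role))
    },

    authenticate = function(entity_id, password, now = as.numeric(Sys.time())) {
      "Password login. Unknown ids and wrong passwords fail identically
       (same condition class and message); comparison always runs over a
       full digest."
      rec <- entities[[entity_id]]
      salt <- if (is.null(rec)) as.raw(rep(0L, 16)) else rec$salt
      stored <- if (is.null(rec)) as.raw(rep(0L, 32)) else rec$digest
      ok <- rawEqualConst(credentialDigest(salt, password), stored) && !is.null(rec)
      if (!ok) fsStop("authError", "authentication failed")
      sid <- paste0(as.character(openssl::rand_bytes(16)), collapse = "")
      sessions[[sid]] <<- list(entity = entity_id, role = rec$role,
                               expires = now + session_ttl)
      journal("authenticate", list(entity = entity_id))
      sid
    },

    requireSession = function(session, op, now = as.numeric(Sys.time())) {
      info <- if (isScalarString(session)) sessions[[session]] else NULL
      if (is.null(info)) fsStop("authError", "authentication failed")
      if (now > info$expires) {
        sessions[[session]] <<- NULL
        fsStop("sessionExpired", "session expired; re-authentication required")
      }
      if (!op %in% ROLE_ALLOW[[info$role]])
        fsStop("authzError", sprintf("role '%s' may not call %s", info$role, op))
      info
    },

    getTask = function(task_id) {
      t <- tasks[[task_id]]
      if (is.null(t)) fsStop("notFoundError", sprintf("unknown task '%s'", task_id))
      t
    },

    submitTask = function(session, task, now = as.numeric(Sys.time())) {
      "Persist task metadata, generate the task signing key, and enqueue the
       master request (aggregator) plus one subtask per station."
      requireSession(session, "submitTask", now)
      validObject(task)
      if (!is.null(tasks[[task@task_id]]))
        fsStop("conflictError", sprintf("task '%s' already exists", task@task_id))
      agg <- entities[[task@aggregator_id]]
      if (is.null(agg) || agg$role != "aggregator")
        fsStop("validationError", sprintf(
          "aggregator '%s' is not a registered aggregator entity", task@aggregator_id))
      for (s in task@station_ids) {
        ent <- entities[[s]]
        if (is.null(ent) || ent$role != "station")
          fsStop("validationError", sprintf("station '%s' is not a registered station entity", s))
      }
      key <- newSigningKey()
      queue <- c(
        list(list(id = paste0(task@task_id, "/master"), addressee = task@aggregator_id,
                  type = "master", task = task, signing_key = key,
                  state = "pending", leased_at = NA_real_)),
        lapply(task@station_ids, function(s)
          list(id = paste0(task@task_id, "/sub/", s), addressee = s,
               type = "subtask", task = task,
               state = "pending", leased_at = NA_real_)))
      statusMat <- matrix("pending", nrow = task@n_iterations,
                          ncol = length(task@station_ids),
                          dimnames = list(NULL, task@station_ids))
      tasks[[task@task_id]] <<- list(
        spec = task, signing_key = key, queue = queue, status = statusMat,
        overall = "created", history = list(), final_model = NULL)
      journal("submit_task", list(task = task@task_id,
                                  stations = task@station_ids,
                                  n_iterations = task@n_iterations))
      invisible(taskStatus(session, task@task_id, now = now))
    },

    pullWork = function(session, now = as.numeric(Sys.time())) {
      "Pull mechanism: return (and lease) work items addressed to the
       calling node. Re-pulling during an active lease returns the same
       item; expired leases are re-queued."
      info <- requireSession(session, "pullWork", now)
      items <- list()
      for (tid in names(tasks)) {
        q <- tasks[[tid]]$queue
        for (i in seq_along(q)) {
          item <- q[[i]]
          if (item$addressee != info$entity) next
          leaseActive <- identical(item$state, "leased") &&
            !is.na(item$leased_at) && now - item$leased_at < lease_ttl
          if (item$state == "pending" || (item$state == "leased" && !leaseActive)) {
            q[[i]]$state <- "leased"; q[[i]]$leased_at <- now
            items[[length(items) + 1L]] <- q[[i]]
          } else if (leaseActive) {
            items[[length(items) + 1L]] <- item
          }
        }
        tasks[[tid]]$queue <<- q
        if (length(items) && tasks[[tid]]$overall == "created")
          tasks[[tid]]$overall <<- "running"
      }
      items
    },

    reportStatus = function(session, task_id, iteration, state, metrics = NULL,
                            now = as.numeric(Sys.time())) {
      "Record a per-(iteration, station) outcome and optional training
       metrics. This is a control/metrics channel: any payload containing
       weight arrays or image data is refused outright."
      info <- requireSession(session, "reportStatus", now)
      t <- getTask(task_id)
      if (!is.null(metrics)) {
        inv <- payloadInventory(metrics)
        for (item in inv)
          if (item$kind %in% c("WeightSet", "PhantomCase", "numeric_array"))
            fsStop("channelError",
                   "status reports must not carry weight or image payloads")
      }
      state <- match.arg(state, c("running", "completed", "aborted"))
      reporter <- info$entity
      if (info$role == "station") {
        if (!reporter %in% t$spec@station_ids)
          fsStop("authzError", sprintf("station '%s' is not on the task roster", reporter))
        if (iteration < 0L || iteration >= t$spec@n_iterations)
          fsStop("validationError", "iteration out of range")
        cur <- t$status[iteration + 1L, reporter]
        allowed <- switch(cur,
          pending = c("running", "completed", "aborted"),
          running = c("completed", "aborted"),
          completed = character(), aborted = character())
        if (!state %in% allowed)
          fsStop("statusRegression", sprintf(
            "illegal status transition %s -> %s for station %s, iteration %d",
            cur, state, reporter, iteration))
        t$status[iteration + 1L, reporter] <- state
      } else if (reporter != t$spec@aggregator_id) {
        fsStop("authzError", "reporter is not addressed by this task")
      }
      if (!is.null(metrics)) {
        if (!is(metrics, "TrainMetrics"))
          fsStop("validationError", "metrics must be a TrainMetrics record")
        t$history[[length(t$history) + 1L]] <- metrics
      }
      if (state == "aborted") t$overall <- "aborted"
      else if (t$overall == "aborted" || t$overall == "created") t$overall <- "running"
      tasks[[task_id]] <<- t
      journal("report_status", list(task = task_id, iteration = iteration,
                                    reporter = reporter, state = state))
      invisible(taskStatusInternal(t))
    },

    reopenIteration = function(session, task_id, iteration,
                               now = as.numeric(Sys.time())) {
      "Aggregator-side re-open after an aborted iteration: the whole
       (iteration, station) row returns to pending and partial completions
       are void."
      requireSession(session, "reopenIteration", now)
      t <- getTask(task_id)
      if (iteration < 0L || iteration >= t$spec@n_iterations)
        fsStop("validationError", "iteration out of range")
      t$status[iteration + 1L, ] <- "pending"
      if (t$overall == "aborted") t$overall <- "running"
      tasks[[task_id]] <<- t
      journal("reopen_iteration", list(task = task_id, iteration = iteration))
      invisible(taskStatusInternal(t))
    },

    storeFinalModel = function(session, task_id, weights,
                               now = as.numeric(Sys.time())) {
      "Persist the single global model of a finished task. Refused while any
       iteration is incomplete, and at most one store per task."
      info <- requireSession(session, "storeFinalModel", now)
      t <- getTask(task_id)
      if (info$entity != t$spec@aggregator_id)
        fsStop("authzError", "only the task's aggregator may store the final model")
      if (!is(weights, "WeightSet")) fsStop("validationError", "payload is not a WeightSet")
      if (!all(t$status == "completed"))
        fsStop("storeRefused", "task has incomplete iterations; final store refused")
      if (!is.null(t$final_model))
        fsStop("conflictError", "final model already stored for this task")
      t$final_model <- weights
      t$overall <- "finished"
      tasks[[task_id]] <<- t
      journal("store_final_model", list(task = task_id,
                                        iteration = weights@meta$iteration))
      invisible(list(task_id = task_id, stored = TRUE))
    },

    fetchFinalModel = function(session, task_id, now = as.numeric(Sys.time())) {
      "Researcher download of the finished global model. While the task is
       running, access is denied — there is no route to intermediates."
      requireSession(session, "fetchFinalModel", now)
      t <- getTask(task_id)
      if (t$overall != "finished" || is.null(t$final_model))
        fsStop("accessDenied", sprintf(
          "task '%s' is not finished; models are not accessible", task_id))
      t$final_model
    },

    taskStatusInternal = function(t) {
      list(task_id = t$spec@task_id, overall = t$overall, iterations = t$status)
    },

    taskStatus = function(session, task_id, now = as.numeric(Sys.time())) {
      "Per-iteration, per-station status matrix plus overall state."
      requireSession(session, "taskStatus", now)
      taskStatusInternal(getTask(task_id))
    },

    storedModelCount = function(task_id = NULL) {
      "Persistence audit: number of WeightSets held (optionally for one
       task). Must be 0 for every unfinished task and 1 per finished task."
      ids <- if (is.null(task_id)) names(tasks) else task_id
      sum(vapply(ids, function(id) !is.null(tasks[[id]]$final_model), TRUE))
    },

    taskHistory = function(task_id) {
      "Metrics records accumulated through reportStatus."
      getTask(task_id)$history
    },

    show = function() {
      cat(sprintf("Coordinator: %d entities, %d active sessions, %d tasks\n",
                  length(entities), length(sessions), length(tasks)))
    }
  )
)
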