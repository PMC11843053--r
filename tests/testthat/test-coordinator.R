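# fully-registered coordinator with one submitted 3-station task
liveCoordinator <- function(n_iterations = 3) {
  co <- Coordinator$new()
  co$registerEntity("alice", "researcher", "pw-alice")
  co$registerEntity("sas", "aggregator", "pw-sas")
  for (s in c("h1", "h2", "h3")) co$registerEntity(s, "station", paste0("pw-", s))
  s <- list(researcher = co$authenticate("alice", "pw-alice"),
            aggregator = co$authenticate("sas", "pw-sas"),
            h1 = co$authenticate("h1", "pw-h1"),
            h2 = co$authenticate("h2", "pw-h2"),
            h3 = co$authenticate("h3", "pw-h3"))
  task <- taskSpec("t1", c("h1", "h2", "h3"), n_iterations,
                   input_params = list(model_seed = 1))
  co$submitTask(s$researcher, task)
  list(co = co, s = s, task = task)
}

test_that("registration stores salted digests and authentication is uniform", {
  co <- Coordinator$new()
  co$registerEntity("alice", "researcher", "s3cret-pw")
  expect_error(co$registerEntity("alice", "researcher", "x"), class = "conflictError")

  ## no recoverable plaintext anywhere in the stored record
  rec <- co$entities[["alice"]]
  expect_false(any(grepl("s3cret-pw", rapply(rec, as.character, how = "unlist"), fixed = TRUE)))
  expect_setequal(names(rec), c("role", "salt", "digest"))

  sid <- co$authenticate("alice", "s3cret-pw")
  expect_true(nzchar(sid))

  ## wrong password and unknown user fail identically
  errWrong <- tryCatch(co$authenticate("alice", "nope"), error = identity)
  errGhost <- tryCatch(co$authenticate("ghost", "nope"), error = identity)
  expect_s3_class(errWrong, "authError")
  expect_s3_class(errGhost, "authError")
  expect_identical(class(errWrong), class(errGhost))
  expect_identical(conditionMessage(errWrong), conditionMessage(errGhost))
})

test_that("expired sessions demand re-authentication", {
  co <- Coordinator$new(session_ttl = 100)
  co$registerEntity("alice", "researcher", "pw")
  now <- 1e9
  sid <- co$authenticate("alice", "pw", now = now)
  expect_error(co$pullWork(sid, now = now + 50), class = "authzError")  # wrong role, but live
  expect_error(co$taskStatus(sid, "none", now = now + 200), class = "sessionExpired")
})

test_that("the role/operation matrix is enforced exhaustively", {
  env <- liveCoordinator()
  ops <- list(
    submitTask = function(sid) env$co$submitTask(sid, taskSpec(
      "t9", c("h1"), 1, input_params = list(model_seed = 1))),
    pullWork = function(sid) env$co$pullWork(sid),
    reportStatus = function(sid) env$co$reportStatus(sid, "t1", 0L, "completed"),
    storeFinalModel = function(sid) env$co$storeFinalModel(sid, "t1",
                                                           randomWeightSet(1)),
    reopenIteration = function(sid) env$co$reopenIteration(sid, "t1", 0L),
    fetchFinalModel = function(sid) env$co$fetchFinalModel(sid, "t1"))
  allow <- list(
    researcher = c("submitTask", "fetchFinalModel"),
    aggregator = c("pullWork", "reportStatus", "storeFinalModel", "reopenIteration"),
    station = c("pullWork", "reportStatus"))
  sessionsByRole <- list(researcher = env$s$researcher,
                         aggregator = env$s$aggregator, station = env$s$h1)
  for (role in names(sessionsByRole)) {
    for (op in names(ops)) {
      if (op %in% allow[[role]]) next
      expect_error(ops[[op]](sessionsByRole[[role]]), class = "authzError",
                   label = sprintf("%s calling %s", role, op))
    }
  }
})

test_that("task submission validates the roster and enqueues master + subtasks", {
  env <- liveCoordinator()
  q <- env$co$tasks[["t1"]]$queue
  expect_length(q, 4)                                   # 1 master + 3 subtasks
  expect_equal(sum(vapply(q, function(i) i$type == "master", TRUE)), 1)
  expect_setequal(vapply(q, function(i) i$addressee, ""),
                  c("sas", "h1", "h2", "h3"))

  expect_error(env$co$submitTask(env$s$researcher, taskSpec(
    "t2", c("h1", "unregistered"), 2, input_params = list(model_seed = 1))),
    class = "validationError")
  expect_error(env$co$submitTask(env$s$researcher, taskSpec(
    "t3", c("h1"), 2, aggregator_id = "h2", input_params = list(model_seed = 1))),
    class = "validationError")
  expect_error(env$co$submitTask(env$s$researcher, env$task), class = "conflictError")
  expect_error(taskSpec("t4", c("h1"), 0))              # n_iterations >= 1
})

test_that("pull is addressee-scoped and lease-idempotent", {
  env <- liveCoordinator()
  got <- env$co$pullWork(env$s$h1)
  expect_length(got, 1)
  expect_equal(got[[1]]$addressee, "h1")
  expect_equal(got[[1]]$type, "subtask")
  again <- env$co$pullWork(env$s$h1)                    # active lease: same item
  expect_length(again, 1)
  expect_equal(again[[1]]$id, got[[1]]$id)
  master <- env$co$pullWork(env$s$aggregator)
  expect_equal(vapply(master, function(i) i$type, ""), "master")
  expect_true(is.raw(master[[1]]$signing_key))          # key travels only to the SAS
})

test_that("status reports are monotone and never carry weights", {
  env <- liveCoordinator()
  env$co$reportStatus(env$s$h1, "t1", 0L, "running")
  env$co$reportStatus(env$s$h1, "t1", 0L, "completed")
  st <- env$co$taskStatus(env$s$researcher, "t1")
  expect_equal(unname(st$iterations[1, "h1"]), "completed")

  ## regression refused
  expect_error(env$co$reportStatus(env$s$h1, "t1", 0L, "running"),
               class = "statusRegression")

  ## abort marks the task aborted until re-opened
  env$co$reportStatus(env$s$h2, "t1", 0L, "aborted")
  expect_equal(env$co$taskStatus(env$s$researcher, "t1")$overall, "aborted")
  env$co$reopenIteration(env$s$aggregator, "t1", 0L)
  st <- env$co$taskStatus(env$s$researcher, "t1")
  expect_true(all(st$iterations[1, ] == "pending"))
  expect_equal(st$overall, "running")

  ## the status channel refuses weight payloads outright
  expect_error(env$co$reportStatus(env$s$h1, "t1", 0L, "completed",
                                   metrics = randomWeightSet(5)),
               class = "channelError")
  ## and off-roster reporters
  co2 <- env$co
  co2$registerEntity("h9", "station", "pw")
  s9 <- co2$authenticate("h9", "pw")
  expect_error(co2$reportStatus(s9, "t1", 0L, "completed"), class = "authzError")
})

test_that("final-model persistence: one model, only after completion", {
  env <- liveCoordinator(n_iterations = 2)
  w <- randomWeightSet(50)

  ## mid-task store refused; nothing persisted; researcher denied
  expect_error(env$co$storeFinalModel(env$s$aggregator, "t1", w),
               class = "storeRefused")
  expect_equal(env$co$storedModelCount("t1"), 0)
  expect_error(env$co$fetchFinalModel(env$s$researcher, "t1"),
               class = "accessDenied")

  for (it in 0:1) for (h in c("h1", "h2", "h3"))
    env$co$reportStatus(env$s[[h]], "t1", it, "completed")
  env$co$storeFinalModel(env$s$aggregator, "t1", w)
  expect_equal(env$co$storedModelCount("t1"), 1)
  expect_error(env$co$storeFinalModel(env$s$aggregator, "t1", w),
               class = "conflictError")

  got <- env$co$fetchFinalModel(env$s$researcher, "t1")
  expect_identical(weightValues(got), weightValues(w))
  expect_error(env$co$fetchFinalModel(env$s$researcher, "unknown-task"),
               class = "notFoundError")
})
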