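test_that("FedAvg reproduces worked examples exactly", {
  a <- weightSet(list(w = c(1, 3)), n_train_samples = 5)
  b <- weightSet(list(w = c(3, 5)), n_train_samples = 5)
  expect_equal(weightValues(fedavgAggregate(list(a, b), "uniform"))$w, c(2, 4))

  z <- weightSet(list(w = c(0, 0)), n_train_samples = 1)
  y <- weightSet(list(w = c(4, 8)), n_train_samples = 3)
  expect_equal(weightValues(fedavgAggregate(list(z, y), "sample_weighted"))$w, c(3, 6))

  ## single model: convex combination collapses to the identity, bit-exact
  solo <- randomWeightSet(31)
  expect_identical(weightValues(fedavgAggregate(list(solo))), weightValues(solo))

  ## pooled sample count and provenance
  agg <- fedavgAggregate(list(z, y))
  expect_equal(weightMeta(agg)$n_train_samples, 4L)
  expect_equal(weightMeta(agg)$origin, "SAS")
})

test_that("FedAvg agrees with a brute-force per-parameter oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    manifest <- weightManifest(randomWeightSet(seed))
    k <- sample(2:5, 1)
    weighting <- sample(c("sample_weighted", "uniform"), 1)
    models <- lapply(seq_len(k), function(j)
      randomWeightSet(seed * 100 + j, manifest = manifest, sdExp = c(-3, 0)))
    got <- weightValues(fedavgAggregate(models, weighting))
    want <- bruteForceAverage(models, weighting)
    maxAbs <- max(mapply(function(a, b) max(abs(a - b)), got, want))
    expect_lt(maxAbs, 1e-6)
    ## convexity: every parameter inside the envelope of its inputs
    for (nm in names(got)) {
      stack <- vapply(models, function(m) as.vector(weightValues(m)[[nm]]),
                      numeric(length(got[[nm]])))
      if (is.null(dim(stack))) stack <- matrix(stack, nrow = 1)
      expect_true(all(as.vector(got[[nm]]) >= apply(stack, 1, min) - 1e-12))
      expect_true(all(as.vector(got[[nm]]) <= apply(stack, 1, max) + 1e-12))
    }
  }
})

test_that("FedAvg refuses incompatible or unweightable inputs", {
  a <- weightSet(list(w = 1:3), n_train_samples = 2)
  b <- weightSet(list(w = 1:4), n_train_samples = 2)
  expect_error(fedavgAggregate(list(a, b)), class = "manifestMismatch")
  z1 <- weightSet(list(w = 1:3), n_train_samples = 0)
  z2 <- weightSet(list(w = 4:6), n_train_samples = 0)
  expect_error(fedavgAggregate(list(z1, z2), "sample_weighted"),
               class = "aggregationError")
  expect_no_error(fedavgAggregate(list(z1, z2), "uniform"))
  expect_error(fedavgAggregate(list()), class = "aggregationError")
})

test_that("task start initializes the barrier and the common initial model", {
  env <- startedAggregator()
  expect_equal(env$sas$status, "waiting")
  expect_setequal(env$sas$expected_stations, c("a", "b", "c"))
  expect_equal(env$sas$current_iteration, 0L)
  ## the broadcast model is exactly init_weights(config, task seed)
  expect_identical(weightValues(env$sas$latest_model),
                   weightValues(initWeights(env$config, 7)))
  expect_error(env$sas$startTask(env$task, env$config, env$key),
               class = "conflictError")
})

test_that("the synchronous barrier fires aggregation exactly once when full", {
  env <- startedAggregator()
  sas <- env$sas
  subs <- lapply(c(a = 0.01, b = 0.02, c = 0.03), function(j)
    submissionFor(sas, "x", jitter = j))
  toks <- sas$currentTokens()

  ack1 <- sas$acceptModelSubmission(toks[["a"]], subs[[1]])
  expect_equal(ack1$status, "waiting")
  expect_equal(sas$current_iteration, 0L)
  ack2 <- sas$acceptModelSubmission(toks[["b"]], subs[[2]])
  expect_equal(ack2$status, "waiting")
  expect_length(sas$events, 0)

  ack3 <- sas$acceptModelSubmission(toks[["c"]], subs[[3]])
  expect_equal(ack3$status, "aggregated")
  expect_equal(sas$current_iteration, 1L)
  expect_length(sas$events, 1)
  expect_equal(sas$events[[1]]$event, "aggregate")
  expect_length(sas$received, 0)
  expect_equal(weightMeta(sas$latest_model)$iteration, 0L)
})

test_that("duplicate, stale and mismatched submissions are refused without side effects", {
  env <- startedAggregator()
  sas <- env$sas
  toks0 <- sas$currentTokens()
  sas$acceptModelSubmission(toks0[["a"]], submissionFor(sas, "a"))

  snapshot <- function() list(it = sas$current_iteration, rec = names(sas$received),
                              model = weightValues(sas$latest_model))
  before <- snapshot()

  ## duplicate station, same iteration: first submission wins
  expect_error(sas$acceptModelSubmission(toks0[["a"]], submissionFor(sas, "a")),
               class = "duplicateSubmission")
  expect_identical(snapshot(), before)

  ## manifest mismatch
  alien <- weightSet(list(q = 1:5), n_train_samples = 3)
  expect_error(sas$acceptModelSubmission(toks0[["b"]], alien),
               class = "manifestMismatch")
  expect_identical(snapshot(), before)

  ## complete iteration 0, then replay an iteration-0 token
  sas$acceptModelSubmission(toks0[["b"]], submissionFor(sas, "b"))
  sas$acceptModelSubmission(toks0[["c"]], submissionFor(sas, "c"))
  expect_equal(sas$current_iteration, 1L)
  after <- list(it = sas$current_iteration, rec = names(sas$received),
                model = weightValues(sas$latest_model))
  expect_error(sas$acceptModelSubmission(toks0[["a"]], submissionFor(sas, "a")),
               class = "tokenReplay")
  expect_identical(list(it = sas$current_iteration, rec = names(sas$received),
                        model = weightValues(sas$latest_model)), after)
})

test_that("global model release follows the previous-iteration contract", {
  env <- startedAggregator(stations = c("a", "b"), n_iterations = 3)
  sas <- env$sas
  init <- weightValues(sas$latest_model)
  toks0 <- sas$currentTokens()

  ## iteration 0: stations download the common initial model
  m0a <- sas$releaseGlobalModel(toks0[["a"]])
  m0b <- sas$releaseGlobalModel(toks0[["b"]])
  expect_identical(weightValues(m0a), init)
  expect_identical(weightValues(m0a), weightValues(m0b))   # read-only, same bytes

  sas$acceptModelSubmission(toks0[["a"]], submissionFor(sas, "a", 0.1))
  sas$acceptModelSubmission(toks0[["b"]], submissionFor(sas, "b", 0.2))

  ## iteration-1 request returns the model aggregated at iteration 0
  toks1 <- sas$currentTokens()
  m1 <- sas$releaseGlobalModel(toks1[["a"]])
  expect_equal(weightMeta(m1)$iteration, 0L)

  ## forged token is refused
  forged <- issueIterationToken(
    tokenClaims("a", sas$task_id, sas$current_iteration), charToRaw("bad-key"))
  expect_error(sas$releaseGlobalModel(forged), class = "tokenForgery")
})

test_that("dropout aborts the iteration, keeps the stored model, and resumes", {
  env <- startedAggregator(stations = c("a", "b"), n_iterations = 4)
  sas <- env$sas
  ## complete iterations 0 and 1
  for (k in 1:2) {
    toks <- sas$currentTokens()
    sas$acceptModelSubmission(toks[["a"]], submissionFor(sas, "a", 0.01 * k))
    sas$acceptModelSubmission(toks[["b"]], submissionFor(sas, "b", 0.02 * k))
  }
  expect_equal(sas$current_iteration, 2L)
  stored <- weightValues(sas$latest_model)

  ## partial submission at iteration 2, then station b drops out
  toks2 <- sas$currentTokens()
  sas$acceptModelSubmission(toks2[["a"]], submissionFor(sas, "a", 0.3))
  expect_length(sas$received, 1)
  sas$reportDropout("b")

  ## partials discarded, latest successful model bit-identical, same iteration
  expect_length(sas$received, 0)
  expect_identical(weightValues(sas$latest_model), stored)
  expect_equal(sas$current_iteration, 2L)

  ## old iteration-2 tokens were revoked by the re-open rotation
  expect_error(sas$acceptModelSubmission(toks2[["a"]], submissionFor(sas, "a", 0.3)),
               class = "tokenReplay")

  ## resume completes iteration 2 (not iteration 0)
  toksNew <- sas$currentTokens()
  sas$acceptModelSubmission(toksNew[["a"]], submissionFor(sas, "a", 0.3))
  sas$acceptModelSubmission(toksNew[["b"]], submissionFor(sas, "b", 0.4))
  expect_equal(weightMeta(sas$latest_model)$iteration, 2L)

  expect_error(sas$reportDropout("nobody"), class = "notFoundError")
})

test_that("finalize releases exactly one model, only at completion", {
  env <- startedAggregator(stations = c("a", "b"), n_iterations = 2)
  sas <- env$sas
  expect_error(sas$finalizeTask(), class = "prematureFinalize")
  for (k in 1:2) {
    toks <- sas$currentTokens()
    sas$acceptModelSubmission(toks[["a"]], submissionFor(sas, "a", 0.01 * k))
    sas$acceptModelSubmission(toks[["b"]], submissionFor(sas, "b", 0.02 * k))
  }
  expect_equal(sas$status, "finished")
  final <- sas$finalizeTask()
  expect_equal(weightMeta(final)$iteration, 1L)   # N=2, 0-based
})
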