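# Shared desk-scale fixtures: a 32x32 grid with a depth-2/base-4 U-Net keeps
# every non-acceptance test in the seconds range while exercising the same
# code paths as the full 64x64 configuration.

tinyProfiles <- function(nPatients = 6, seed = 100) {
  lapply(1:3, function(i)
    siteProfile(paste0("s", i), n_patients = nPatients,
                intensity_offset = (i - 2) * 10, noise_sd = 3,
                tumor_radius_range = c(3, 5), lung_ellipse_params = c(12, 9),
                grid = c(32L, 32L), seed = seed + i))
}

tinyModelConfig <- function(batch_size = 2) {
  modelConfig(depth = 2, base_filters = 4, input_shape = c(32L, 32L),
              batch_size = batch_size)
}

tinyFederationConfig <- function(n_iterations = 2, steps = 5, nPatients = 6, ...) {
  resolveConfig(list(
    sites = tinyProfiles(nPatients),
    n_iterations = n_iterations, steps_per_iteration = steps,
    model = list(depth = 2, base_filters = 4, input_shape = c(32L, 32L)),
    ...))
}

.tinyCohortCache <- new.env(parent = emptyenv())
tinyCohort <- function() {
  if (is.null(.tinyCohortCache$c)) {
    .tinyCohortCache$c <- generatePartitionedCohort(tinyProfiles(), 0.8)
  }
  .tinyCohortCache$c
}

# random WeightSet over a random manifest, for serialization/FedAvg fuzzing;
# sdExp bounds the log10 scale of the entries (network weights are O(1))
randomWeightSet <- function(seed, manifest = NULL, n_train_samples = NULL,
                            sdExp = c(-3, 2)) {
  set.seed(seed)
  if (is.null(manifest)) {
    nEntries <- sample(1:6, 1)
    manifest <- lapply(seq_len(nEntries), function(i) {
      if (runif(1) < 0.5) sample(1:40, 1) else c(sample(1:12, 1), sample(1:12, 1))
    })
    names(manifest) <- paste0("layer", seq_len(nEntries), ".",
                              sample(c("W", "b", "k"), nEntries, replace = TRUE))
  }
  values <- lapply(manifest, function(shape) {
    v <- rnorm(prod(shape), sd = 10^runif(1, sdExp[1], sdExp[2]))
    if (length(shape) > 1) dim(v) <- shape
    v
  })
  if (is.null(n_train_samples)) n_train_samples <- sample(1:500, 1)
  weightSet(values, task_id = "fuzz", iteration = 0L, origin = "SAS",
            n_train_samples = n_train_samples)
}

# independent brute-force FedAvg oracle: plain double loop over flattened
# parameters, no shared code with fedavgAggregate
bruteForceAverage <- function(models, weighting = "sample_weighted") {
  n <- vapply(models, function(m) as.numeric(weightMeta(m)$n_train_samples), 0)
  alpha <- if (weighting == "sample_weighted") n / sum(n) else rep(1 / length(models), length(models))
  ref <- weightValues(models[[1]])
  out <- ref
  for (nm in names(ref)) {
    acc <- numeric(length(ref[[nm]]))
    for (k in seq_along(models)) {
      vk <- as.vector(weightValues(models[[k]])[[nm]])
      for (j in seq_along(acc)) acc[j] <- acc[j] + alpha[k] * vk[j]
    }
    dim(acc) <- dim(ref[[nm]])
    out[[nm]] <- acc
  }
  out
}

# minimal live aggregator with a started task, for token/barrier tests
startedAggregator <- function(stations = c("a", "b", "c"), n_iterations = 3,
                              config = modelConfig(depth = 1, base_filters = 1,
                                                   input_shape = c(8L, 8L)),
                              seed = 7) {
  key <- newSigningKey()
  task <- taskSpec("tok-task", stations, n_iterations,
                   input_params = list(model_seed = seed))
  sas <- SecureAggregator$new()
  sas$startTask(task, config, key)
  list(sas = sas, key = key, task = task, config = config)
}

# WeightSet matching an aggregator's manifest, perturbed per station
submissionFor <- function(sas, station, jitter = 0.01) {
  vals <- lapply(weightValues(sas$latest_model), function(v) v + jitter)
  weightSet(vals, task_id = sas$task_id, iteration = sas$current_iteration,
            origin = station, n_train_samples = 5L)
}
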