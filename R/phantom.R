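## Synthetic multi-site CT phantom generator.
##
## Stands in for a consortium's preprocessed lung-CT slices: each "site" holds
## disjoint synthetic patients (horizontal partitioning), with per-site
## intensity calibration offsets, noise levels, tumor size distributions and
## lung geometry emulating multi-hospital heterogeneity. Every case is a pure
## function of (site seed, case index), so cohorts regenerate bit-identically
## and adding patients never perturbs existing ones.

#' Site profile for phantom generation
#'
#' Describes one simulated hospital: how many patients it holds and the
#' site-level acquisition characteristics (additive grey-level calibration
#' shift, noise standard deviation, tumor radius range in pixels, lung ellipse
#' semi-axes in pixels) plus the site RNG seed.
#'
#' @slot site_id Short unique site identifier.
#' @slot n_patients Number of patients at the site (>= 1).
#' @slot intensity_offset Additive grey-level shift applied to the whole
#'   image (arbitrary units; emulates scanner calibration differences).
#' @slot noise_sd Standard deviation of additive Gaussian noise (grey levels).
#' @slot tumor_radius_range Length-2 numeric, min/max tumor radius in pixels.
#' @slot lung_ellipse_params Length-2 numeric, lung semi-axes in pixels
#'   (along image columns and rows respectively).
#' @slot grid Length-2 integer, image grid (rows, cols); default 64 x 64.
#' @slot seed Non-negative integer site seed.
#' @export
setClass("SiteProfile", representation(
  site_id = "character", n_patients = "integer",
  intensity_offset = "numeric", noise_sd = "numeric",
  tumor_radius_range = "numeric", lung_ellipse_params = "numeric",
  grid = "integer", seed = "integer"
))

setValidity("SiteProfile", function(object) {
  msg <- character()
  if (!isScalarString(object@site_id)) msg <- c(msg, "site_id must be a non-empty string")
  if (!isCount(object@n_patients)) msg <- c(msg, "n_patients must be >= 1")
  if (length(object@noise_sd) != 1L || object@noise_sd < 0)
    msg <- c(msg, "noise_sd must be a single non-negative number")
  rr <- object@tumor_radius_range
  if (length(rr) != 2L || rr[1] <= 0 || rr[1] > rr[2])
    msg <- c(msg, "tumor_radius_range must satisfy 0 < min <= max")
  if (length(rr) == 2L && rr[1] < 2)
    msg <- c(msg, "minimum tumor radius must be >= 2 pixels (guarantees a non-empty mask)")
  le <- object@lung_ellipse_params
  if (length(le) != 2L || any(le <= 0)) msg <- c(msg, "lung_ellipse_params must be two positive semi-axes")
  ## tumor (with up to +/-20% axis jitter and boundary perturbation) must fit
  ## inside the lung ellipse
  if (length(rr) == 2L && length(le) == 2L && rr[2] * 1.3 > min(le))
    msg <- c(msg, "tumor radius bounds do not fit inside the lung ellipse (max radius * 1.3 must be <= min semi-axis)")
  g <- object@grid
  if (length(g) != 2L || any(g < 16L)) msg <- c(msg, "grid must be two dims >= 16")
  if (length(le) == 2L && length(g) == 2L && (2 * le[1] >= g[2] || 2 * le[2] >= g[1]))
    msg <- c(msg, "lung ellipse must fit inside the grid")
  if (length(object@seed) != 1L || is.na(object@seed) || object@seed < 0)
    msg <- c(msg, "seed must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a SiteProfile
#'
#' @param site_id Short unique site identifier.
#' @param n_patients Number of patients (>= 1).
#' @param intensity_offset Additive grey-level shift (default 0).
#' @param noise_sd Gaussian noise SD in grey levels (default 5).
#' @param tumor_radius_range Min/max tumor radius in pixels (default c(4, 9)).
#' @param lung_ellipse_params Lung semi-axes in pixels (default c(24, 17)).
#' @param grid Image grid rows x cols (default c(64, 64)).
#' @param seed Site seed (default 0).
#' @return A [SiteProfile-class] object.
#' @export
siteProfile <- function(site_id, n_patients, intensity_offset = 0,
                        noise_sd = 5, tumor_radius_range = c(4, 9),
                        lung_ellipse_params = c(24, 17), grid = c(64L, 64L),
                        seed = 0) {
  new("SiteProfile", site_id = as.character(site_id),
      n_patients = as.integer(n_patients),
      intensity_offset = as.numeric(intensity_offset),
      noise_sd = as.numeric(noise_sd),
      tumor_radius_range = as.numeric(tumor_radius_range),
      lung_ellipse_params = as.numeric(lung_ellipse_params),
      grid = as.integer(grid), seed = as.integer(seed))
}

setMethod("show", "SiteProfile", function(object) {
  cat(sprintf("SiteProfile '%s': %d patients, %dx%d grid, offset %+g, noise sd %g, tumor r [%g, %g], seed %d\n",
              object@site_id, object@n_patients, object@grid[1], object@grid[2],
              object@intensity_offset, object@noise_sd,
              object@tumor_radius_range[1], object@tumor_radius_range[2], object@seed))
})

#' One synthetic patient: a 2D slice and its binary tumor mask
#'
#' @slot patient_id Globally unique patient identifier (embeds the site id).
#' @slot site_id Site identifier.
#' @slot image Numeric matrix (grey levels, float32-representable values).
#' @slot mask Integer matrix of 0/1, same shape, at least one foreground pixel.
#' @export
setClass("PhantomCase", representation(
  patient_id = "character", site_id = "character",
  image = "matrix", mask = "matrix"
))

setValidity("PhantomCase", function(object) {
  msg <- character()
  if (!isScalarString(object@patient_id)) msg <- c(msg, "patient_id must be a non-empty string")
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask shapes differ")
  mv <- unique(as.vector(object@mask))
  if (!all(mv %in% c(0L, 1L))) msg <- c(msg, "mask values must be 0/1")
  if (sum(object@mask) < 1L) msg <- c(msg, "mask must contain at least one foreground pixel")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))
#' @export
setGeneric("caseImage", function(x) standardGeneric("caseImage"))
#' @export
setGeneric("caseMask", function(x) standardGeneric("caseMask"))

#' @describeIn PhantomCase-class Patient identifier.
#' @param x A `PhantomCase`.
#' @export
setMethod("patientId", "PhantomCase", function(x) x@patient_id)
#' @describeIn PhantomCase-class Site identifier.
#' @export
setMethod("siteId", "PhantomCase", function(x) x@site_id)
#' @describeIn PhantomCase-class Image matrix.
#' @export
setMethod("caseImage", "PhantomCase", function(x) x@image)
#' @describeIn PhantomCase-class Binary mask matrix.
#' @export
setMethod("caseMask", "PhantomCase", function(x) x@mask)

setMethod("show", "PhantomCase", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomCase %s (site %s): %dx%d image, %d tumor pixels\n",
              object@patient_id, object@site_id, d[1], d[2], sum(object@mask)))
})

#' Binary mask of the lung ellipse interior on a grid
#'
#' @param grid Length-2 integer grid (rows, cols).
#' @param lung_ellipse_params Semi-axes (cols, rows) in pixels.
#' @return Logical matrix, TRUE inside the lung ellipse.
#' @export
lungRegion <- function(grid, lung_ellipse_params) {
  H <- grid[1]; W <- grid[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  a <- lung_ellipse_params[1]; b <- lung_ellipse_params[2]
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

## Grey-level model of the phantom: dark background, brighter lung field,
## bright tumor blob. Values chosen so a tumor/lung contrast survives
## realistic per-site offsets and noise.
PHANTOM_BG <- 20
PHANTOM_LUNG <- 60
PHANTOM_TUMOR <- 140

#' Generate one deterministic phantom case
#'
#' The case is a pure function of `(profile@seed, case_index)`: a dark
#' background, a brighter lung ellipse, one quasi-elliptical tumor blob with
#' area-preserving axis jitter (up to +/-20%), random rotation and smooth
#' low-frequency boundary perturbation, a site-wide additive intensity
#' offset, and additive Gaussian noise. The mask is the tumor blob,
#' guaranteed to lie inside the lung ellipse. Intensities are quantized to
#' the float32 grid so NIfTI round trips are lossless.
#'
#' @param profile A [SiteProfile-class].
#' @param case_index 0-based patient index, `< profile@n_patients`.
#' @return A [PhantomCase-class].
#' @export
#' @examples
#' p <- siteProfile("A", n_patients = 2, seed = 7)
#' case <- generateCase(p, 0)
#' sum(caseMask(case)) > 0
generateCase <- function(profile, case_index) {
  validObject(profile)
  if (!isCount(case_index, min = 0L) || case_index >= profile@n_patients)
    fsStop("boundsError", sprintf("case_index %s out of range [0, %d)",
                                  format(case_index), profile@n_patients))
  H <- profile@grid[1]; W <- profile@grid[2]
  La <- profile@lung_ellipse_params[1]; Lb <- profile@lung_ellipse_params[2]
  cy0 <- (H + 1) / 2; cx0 <- (W + 1) / 2
  lung <- lungRegion(profile@grid, profile@lung_ellipse_params)

  caseSeed <- deriveSeed(profile@seed, 11L, case_index)
  out <- withSeed(caseSeed, {
    r <- runif(1, profile@tumor_radius_range[1], profile@tumor_radius_range[2])
    f <- exp(runif(1, -log(1.2), log(1.2)))       # area-preserving axis jitter
    a <- r * f; b <- r / f
    phi <- runif(1, 0, pi)
    rho <- sqrt(runif(1)) * 0.55                  # tumor center well inside lung
    theta <- runif(1, 0, 2 * pi)
    ct <- cx0 + rho * cos(theta) * (La - max(a, b) * 1.15)
    rt <- cy0 + rho * sin(theta) * (Lb - max(a, b) * 1.15)
    ck <- rnorm(3, 0, 0.03)                       # smooth boundary harmonics
    psi <- runif(3, 0, 2 * pi)

    y <- matrix(seq_len(H), H, W)
    x <- matrix(seq_len(W), H, W, byrow = TRUE)
    dx <- x - ct; dy <- y - rt
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    ang <- atan2(dy, dx)
    delta <- ck[1] * cos(ang + psi[1]) + ck[2] * cos(2 * ang + psi[2]) +
      ck[3] * cos(3 * ang + psi[3])
    tumor <- ((u / a)^2 + (v / b)^2 <= (1 + delta)^2) & lung

    img <- matrix(PHANTOM_BG, H, W)
    img[lung] <- PHANTOM_LUNG
    img[tumor] <- PHANTOM_TUMOR
    img <- img + profile@intensity_offset +
      matrix(rnorm(H * W, 0, profile@noise_sd), H, W)
    list(img = img, tumor = tumor)
  })

  mask <- matrix(0L, H, W)
  mask[out$tumor] <- 1L
  new("PhantomCase",
      patient_id = sprintf("%s_%04d", profile@site_id, case_index),
      site_id = profile@site_id,
      image = float32(out$img), mask = mask)
}

#' Horizontally partitioned multi-site cohort
#'
#' @slot cases Named list (by site id) of lists of [PhantomCase-class].
#' @slot assignments Named list (by site id) of `list(train=, validation=)`
#'   patient-id character vectors; every case is in exactly one of the two.
#' @slot split_fraction Train fraction in (0, 1).
#' @export
setClass("PartitionedCohort", representation(
  cases = "list", assignments = "list", split_fraction = "numeric"
))

setValidity("PartitionedCohort", function(object) {
  msg <- character()
  if (object@split_fraction <= 0 || object@split_fraction >= 1)
    msg <- c(msg, "split_fraction must lie in (0, 1)")
  ids <- lapply(object@cases, function(cs) vapply(cs, patientId, ""))
  all_ids <- unlist(ids, use.names = FALSE)
  if (anyDuplicated(all_ids)) msg <- c(msg, "patient_id sets of sites are not disjoint")
  for (s in names(object@cases)) {
    asg <- object@assignments[[s]]
    both <- c(asg$train, asg$validation)
    if (!setequal(both, ids[[s]]) || anyDuplicated(both))
      msg <- c(msg, sprintf("site %s: cases not split into exactly one of train/validation", s))
  }
  if (length(msg)) msg else TRUE
})

#' Generate a partitioned multi-site cohort
#'
#' Generates every site's patients deterministically from its profile and
#' assigns each to train or validation. The validation count is
#' `max(1, round((1 - split_fraction) * n))`; a site with a single patient is
#' rejected because every station must hold a validation sample.
#'
#' @param profiles List of [SiteProfile-class] with unique site ids.
#' @param split_fraction Train fraction in (0, 1), default 0.8.
#' @return A [PartitionedCohort-class].
#' @export
generatePartitionedCohort <- function(profiles, split_fraction = 0.8) {
  if (!length(profiles)) fsStop("configError", "at least one site profile is required")
  sids <- vapply(profiles, function(p) p@site_id, "")
  if (anyDuplicated(sids))
    fsStop("configError", sprintf("duplicate site_id: %s", sids[duplicated(sids)][1]))
  if (!is.numeric(split_fraction) || length(split_fraction) != 1L ||
      split_fraction <= 0 || split_fraction >= 1)
    fsStop("configError", "split_fraction must lie in (0, 1)")
  cases <- list(); assignments <- list()
  for (p in profiles) {
    n <- p@n_patients
    if (n == 1L)
      fsStop("configError", sprintf(
        "site %s has a single patient; cannot reserve a validation sample", p@site_id))
    cs <- lapply(seq_len(n) - 1L, function(i) generateCase(p, i))
    nVal <- max(1L, as.integer(round((1 - split_fraction) * n)))
    if (nVal >= n) nVal <- n - 1L
    valIdx <- withSeed(deriveSeed(p@seed, 13L), sample(n, nVal))
    ids <- vapply(cs, patientId, "")
    cases[[p@site_id]] <- cs
    assignments[[p@site_id]] <- list(train = ids[-valIdx], validation = ids[valIdx])
  }
  new("PartitionedCohort", cases = cases, assignments = assignments,
      split_fraction = split_fraction)
}

#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
#' @describeIn PartitionedCohort-class Site identifiers.
#' @param x A `PartitionedCohort`.
#' @export
setMethod("siteIds", "PartitionedCohort", function(x) names(x@cases))

#' Extract the cases of one site
#'
#' @param cohort A [PartitionedCohort-class].
#' @param site_id Site identifier.
#' @param subset `"all"`, `"train"` or `"validation"`.
#' @return List of [PhantomCase-class].
#' @export
siteCases <- function(cohort, site_id, subset = c("all", "train", "validation")) {
  subset <- match.arg(subset)
  if (!site_id %in% names(cohort@cases))
    fsStop("notFoundError", sprintf("unknown site '%s'", site_id))
  cs <- cohort@cases[[site_id]]
  if (subset == "all") return(cs)
  keep <- cohort@assignments[[site_id]][[subset]]
  cs[vapply(cs, patientId, "") %in% keep]
}

setMethod("show", "PartitionedCohort", function(object) {
  n <- vapply(object@cases, length, 0L)
  cat(sprintf("PartitionedCohort: %d sites, %d patients total (train fraction %g)\n",
              length(n), sum(n), object@split_fraction))
  for (s in names(object@cases)) {
    asg <- object@assignments[[s]]
    cat(sprintf("  %s: %d train / %d validation\n", s,
                length(asg$train), length(asg$validation)))
  }
})

## ---- NIfTI I/O ---------------------------------------------------------

casePaths <- function(patient_id, directory) {
  c(image = file.path(directory, paste0(patient_id, "_img.nii.gz")),
    mask = file.path(directory, paste0(patient_id, "_msk.nii.gz")))
}

#' Write a phantom case as a NIfTI-1 image/mask pair
#'
#' The image is stored as float32 and the mask as uint8, both with an
#' identity affine. Existing files are not overwritten unless `force = TRUE`.
#'
#' @param case A [PhantomCase-class].
#' @param directory Output directory (created if missing).
#' @param force Overwrite existing files? Default FALSE.
#' @return Named character vector `c(image=, mask=)` of written paths.
#' @export
writeCaseNifti <- function(case, directory, force = FALSE) {
  validObject(case)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) fsStop("ioError", sprintf("cannot create directory %s", directory))
  paths <- casePaths(case@patient_id, directory)
  if (!force && any(file.exists(paths)))
    fsStop("overwriteError", sprintf(
      "files for patient %s already exist (use force = TRUE to overwrite)", case@patient_id))
  RNifti::writeNifti(case@image, paths[["image"]], datatype = "float")
  RNifti::writeNifti(matrix(as.integer(case@mask), nrow(case@mask)), paths[["mask"]],
                     datatype = "uint8")
  paths
}

#' Read a phantom case from a NIfTI-1 image/mask pair
#'
#' Validates that image and mask have identical shapes and that the mask is
#' strictly binary before constructing the case. Identifiers default to
#' parsing from the file name (`<site>_<index>_img.nii.gz`).
#'
#' @param image_path Path to the image NIfTI.
#' @param mask_path Path to the mask NIfTI.
#' @param patient_id,site_id Optional explicit identifiers.
#' @return A [PhantomCase-class].
#' @export
readCaseNifti <- function(image_path, mask_path, patient_id = NULL, site_id = NULL) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) fsStop("ioError", sprintf("file not found: %s", p))
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  img <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
  mskDim <- dim(msk)
  mskM <- matrix(as.numeric(msk), mskDim[1], mskDim[2])
  if (!identical(dim(img), dim(mskM)))
    fsStop("formatError", sprintf("image shape %s does not match mask shape %s",
                                  paste(dim(img), collapse = "x"),
                                  paste(dim(mskM), collapse = "x")))
  if (!all(as.vector(mskM) %in% c(0, 1)))
    fsStop("formatError", "mask is not binary (values outside {0,1})")
  if (is.null(patient_id))
    patient_id <- sub("_img\\.nii(\\.gz)?$", "", basename(image_path))
  if (is.null(site_id)) site_id <- sub("_[0-9]+$", "", patient_id)
  mi <- matrix(as.integer(mskM), nrow(mskM))
  new("PhantomCase", patient_id = patient_id, site_id = site_id,
      image = img, mask = mi)
}

#' Write a whole cohort in the station directory layout
#'
#' Produces `site_<id>/{train,validation}/<patient>_{img,msk}.nii.gz` under
#' `root` — the persistent train and validation folders a data station serves
#' its local worker from.
#'
#' @param cohort A [PartitionedCohort-class].
#' @param root Output root directory.
#' @param force Overwrite existing files? Default FALSE.
#' @return Invisibly, a character vector of site root directories (named by site).
#' @export
writeCohortNifti <- function(cohort, root, force = FALSE) {
  validObject(cohort)
  out <- character()
  for (s in siteIds(cohort)) {
    sdir <- file.path(root, paste0("site_", s))
    for (subset in c("train", "validation"))
      for (case in siteCases(cohort, s, subset))
        writeCaseNifti(case, file.path(sdir, subset), force = force)
    out[[s]] <- sdir
  }
  invisible(out)
}

#' Read site profiles from a JSON file
#'
#' The file holds an array of objects with the [siteProfile()] fields
#' (`site_id`, `n_patients`, optional `intensity_offset`, `noise_sd`,
#' `tumor_radius_range`, `lung_ellipse_params`, `grid`, `seed`).
#'
#' @param path JSON file path.
#' @return List of [SiteProfile-class].
#' @export
siteProfilesFromJSON <- function(path) {
  if (!file.exists(path)) fsStop("ioError", sprintf("file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(raw)) fsStop("configError", "profile file contains no sites")
  lapply(raw, function(entry) {
    known <- c("site_id", "n_patients", "intensity_offset", "noise_sd",
               "tumor_radius_range", "lung_ellipse_params", "grid", "seed")
    bad <- setdiff(names(entry), known)
    if (length(bad))
      fsStop("configError", sprintf("unknown profile keys: %s", paste(bad, collapse = ", ")))
    entry <- lapply(entry, function(v) unlist(v, use.names = FALSE))
    do.call(siteProfile, entry)
  })
}

#' Default heterogeneous three-site study profiles
#'
#' The stock desk-scale study conditions: three sites of 50 patients each
#' (40 train / 10 validation at the default 0.8 split) with distinct intensity
#' offsets, noise levels, tumor size ranges and lung geometry.
#'
#' @param n_patients Patients per site, default 50.
#' @param seed Base seed; per-site seeds are derived from it.
#' @return List of three [SiteProfile-class].
#' @export
defaultSiteProfiles <- function(n_patients = 50, seed = 2026) {
  list(
    siteProfile("siteA", n_patients, intensity_offset = 0, noise_sd = 4,
                tumor_radius_range = c(4, 9), lung_ellipse_params = c(24, 17),
                seed = deriveSeed(seed, 1L)),
    siteProfile("siteB", n_patients, intensity_offset = 18, noise_sd = 6,
                tumor_radius_range = c(5, 10), lung_ellipse_params = c(22, 16),
                seed = deriveSeed(seed, 2L)),
    siteProfile("siteC", n_patients, intensity_offset = -12, noise_sd = 8,
                tumor_radius_range = c(4, 8), lung_ellipse_params = c(25, 18),
                seed = deriveSeed(seed, 3L))
  )
}
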