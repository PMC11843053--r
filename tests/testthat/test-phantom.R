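test_that("case generation is deterministic and reflects site heterogeneity", {
  p <- siteProfile("A", n_patients = 3, noise_sd = 0, tumor_radius_range = c(4, 4),
                   seed = 5)
  c1 <- generateCase(p, 0)
  c2 <- generateCase(p, 0)
  expect_identical(caseImage(c1), caseImage(c2))
  expect_identical(caseMask(c1), caseMask(c2))
  expect_false(identical(caseMask(c1), caseMask(generateCase(p, 1))))

  ## fixed radius 4, no noise: rasterized area stays between the r=3.5 and
  ## r=4.5 discs
  px <- sum(caseMask(c1))
  expect_gte(px, pi * 3.5^2)
  expect_lte(px, pi * 4.5^2)

  ## a pure intensity offset shifts the lung-field mean by exactly that much
  pOff <- siteProfile("A", n_patients = 3, noise_sd = 0, tumor_radius_range = c(4, 4),
                      intensity_offset = 50, seed = 5)
  lung <- lungRegion(p@grid, p@lung_ellipse_params)
  shift <- mean(caseImage(generateCase(pOff, 0))[lung]) - mean(caseImage(c1)[lung])
  expect_equal(shift, 50, tolerance = 1e-4)

  ## out-of-range index
  expect_error(generateCase(p, 3), class = "boundsError")
  expect_error(generateCase(p, -1), class = "boundsError")
})

test_that("masks are non-empty, binary, and contained in the lung ellipse", {
  for (p in tinyProfiles(4)) {
    lung <- lungRegion(p@grid, p@lung_ellipse_params)
    for (i in 0:(p@n_patients - 1)) {
      m <- caseMask(generateCase(p, i))
      expect_true(all(m %in% c(0L, 1L)))
      expect_gte(sum(m), 1)
      expect_true(all(m[!lung] == 0L))
    }
  }
})

test_that("cohorts are horizontally partitioned with the documented split rule", {
  profiles <- list(
    siteProfile("h1", 10, grid = c(32L, 32L), lung_ellipse_params = c(12, 9),
                tumor_radius_range = c(3, 5), seed = 1),
    siteProfile("h2", 20, grid = c(32L, 32L), lung_ellipse_params = c(12, 9),
                tumor_radius_range = c(3, 5), seed = 2),
    siteProfile("h3", 30, grid = c(32L, 32L), lung_ellipse_params = c(12, 9),
                tumor_radius_range = c(3, 5), seed = 3))
  cohort <- generatePartitionedCohort(profiles, 0.8)
  ids <- lapply(siteIds(cohort), function(s)
    vapply(siteCases(cohort, s), patientId, ""))
  expect_equal(sum(lengths(ids)), 60)
  for (i in 1:2) for (j in (i + 1):3)
    expect_length(intersect(ids[[i]], ids[[j]]), 0)

  ## split rule: validation count = max(1, round((1-f) n))
  expect_length(siteCases(cohort, "h1", "train"), 8)
  expect_length(siteCases(cohort, "h1", "validation"), 2)
  ## every case in exactly one subset
  for (s in siteIds(cohort)) {
    tr <- vapply(siteCases(cohort, s, "train"), patientId, "")
    va <- vapply(siteCases(cohort, s, "validation"), patientId, "")
    expect_length(intersect(tr, va), 0)
    expect_setequal(c(tr, va), vapply(siteCases(cohort, s), patientId, ""))
  }

  ## degenerate and invalid configurations
  expect_error(generatePartitionedCohort(list(
    siteProfile("solo", 1, grid = c(32L, 32L), lung_ellipse_params = c(12, 9),
                tumor_radius_range = c(3, 5))), 0.8), class = "configError")
  expect_error(generatePartitionedCohort(list(profiles[[1]], profiles[[1]]), 0.8),
               class = "configError")
  expect_error(generatePartitionedCohort(profiles, 1.2), class = "configError")
})

test_that("adding patients to a site never perturbs existing cases", {
  base <- siteProfile("grow", 3, grid = c(32L, 32L), lung_ellipse_params = c(12, 9),
                      tumor_radius_range = c(3, 5), seed = 42)
  bigger <- siteProfile("grow", 5, grid = c(32L, 32L), lung_ellipse_params = c(12, 9),
                        tumor_radius_range = c(3, 5), seed = 42)
  for (i in 0:2)
    expect_identical(caseImage(generateCase(base, i)),
                     caseImage(generateCase(bigger, i)))
})

test_that("NIfTI image/mask round trips are lossless and validated", {
  case <- siteCases(tinyCohort(), "s1")[[1]]
  dir <- withr::local_tempdir()
  paths <- writeCaseNifti(case, dir)
  back <- readCaseNifti(paths[["image"]], paths[["mask"]])
  expect_identical(caseImage(back), caseImage(case))
  expect_identical(caseMask(back), caseMask(case))
  expect_identical(patientId(back), patientId(case))

  ## mask file holds only 0/1 voxels
  voxels <- as.vector(RNifti::readNifti(paths[["mask"]]))
  expect_true(all(voxels %in% c(0, 1)))

  ## overwrite policy
  expect_error(writeCaseNifti(case, dir), class = "overwriteError")
  expect_no_error(writeCaseNifti(case, dir, force = TRUE))

  ## shape mismatch between image and mask
  small <- matrix(0L, 16, 16); small[4:6, 4:6] <- 1L
  RNifti::writeNifti(small, file.path(dir, "bad_msk.nii.gz"), datatype = "uint8")
  expect_error(readCaseNifti(paths[["image"]], file.path(dir, "bad_msk.nii.gz")),
               class = "formatError")

  ## non-binary mask is refused
  tri <- caseMask(case); tri[which(tri == 1L)[1]] <- 2L
  RNifti::writeNifti(tri, file.path(dir, "tri_msk.nii.gz"), datatype = "uint8")
  expect_error(readCaseNifti(paths[["image"]], file.path(dir, "tri_msk.nii.gz")),
               class = "formatError")

  expect_error(readCaseNifti("no/such/file.nii.gz", paths[["mask"]]),
               class = "ioError")
})

test_that("cohort export uses the station directory layout", {
  root <- withr::local_tempdir()
  cohort <- tinyCohort()
  writeCohortNifti(cohort, root)
  for (s in siteIds(cohort)) {
    nTrain <- length(siteCases(cohort, s, "train"))
    files <- list.files(file.path(root, paste0("site_", s), "train"))
    expect_length(files, 2 * nTrain)   # image + mask per patient
  }
})

test_that("site profiles load from JSON with schema validation", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(site_id = "j1", n_patients = 4, seed = 1,
         tumor_radius_range = c(3, 5), lung_ellipse_params = c(12, 9),
         grid = c(32, 32)),
    list(site_id = "j2", n_patients = 3, intensity_offset = 12, seed = 2,
         tumor_radius_range = c(3, 5), lung_ellipse_params = c(12, 9),
         grid = c(32, 32))), auto_unbox = TRUE), path)
  profs <- siteProfilesFromJSON(path)
  expect_length(profs, 2)
  expect_equal(profs[[2]]@intensity_offset, 12)
  expect_identical(caseImage(generateCase(profs[[1]], 0)),
                   caseImage(generateCase(siteProfile(
                     "j1", 4, tumor_radius_range = c(3, 5),
                     lung_ellipse_params = c(12, 9), grid = c(32L, 32L),
                     seed = 1), 0)))

  writeLines('[{"site_id": "x", "n_patients": 2, "noize": 1}]', path)
  expect_error(siteProfilesFromJSON(path), "noize", class = "configError")
})
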