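coarse_spec <- function(...) {
  cohortSpec(n_patients = 6, seed = 11, ...)
}

test_that("cohort simulation is reproducible under the master seed", {
  mask <- test_phantom_mask()
  spec <- coarse_spec(prevalence = c(bowel = .5, lung = .5, thyroid = .5))
  a <- simulateCohort(spec, model = uptakeModel(), mask = mask)
  b <- simulateCohort(spec, model = uptakeModel(), mask = mask)
  expect_identical(a@truth, b@truth)
  expect_identical(a@profiles, b@profiles)
  expect_gt(nrow(a@truth), 0)
})

test_that("zero prevalence yields an event-free cohort with empty truth", {
  mask <- test_phantom_mask()
  spec <- coarse_spec(prevalence = c(bowel = 0, lung = 0, thyroid = 0))
  coh <- simulateCohort(spec, model = uptakeModel(), mask = mask)
  expect_equal(nrow(coh@truth), 0)
  expect_true(all(table(coh@profiles$patient_id) > 0))
})

test_that("tiny expected event counts raise a warning, not an error", {
  mask <- test_phantom_mask()
  spec <- cohortSpec(n_patients = 2, seed = 3,
                     prevalence = c(bowel = .01, lung = .01, thyroid = .01))
  expect_warning(simulateCohort(spec, model = uptakeModel(), mask = mask),
                 "expected event count")
})

test_that("schedules have a pre-treatment baseline and >= 2 scans", {
  mask <- test_phantom_mask()
  spec <- cohortSpec(n_patients = 20, seed = 5)
  plan <- iraePET:::.plan_cohort(spec, mask, uptakeModel())
  for (pt in plan) {
    expect_gte(length(pt$days), 2)
    expect_lt(pt$days[1], 0)
    expect_true(all(pt$days[-1] > 0))
    expect_true(all(diff(pt$days) > 0))
  }
  n_scans <- vapply(plan, function(p) length(p$days), numeric(1))
  expect_equal(median(n_scans), 4, tolerance = 0.5)
})

test_that("event counts across seeds match the binomial prevalence design", {
  mask <- toy_mask()  # planning only; no rendering
  counts <- matrix(0, 20, 3, dimnames = list(NULL, c("bowel", "lung",
                                                     "thyroid")))
  for (s in 1:20) {
    spec <- cohortSpec(n_patients = 58, seed = 100 + s)
    plan <- iraePET:::.plan_cohort(spec, mask, uptakeModel())
    for (pt in plan) for (ev in pt$events)
      counts[s, ev@organ] <- counts[s, ev@organ] + 1
  }
  expected <- c(bowel = 6, lung = 5, thyroid = 9)
  se <- sqrt(expected * (1 - expected / 58)) / sqrt(20)
  for (organ in names(expected))
    expect_lt(abs(mean(counts[, organ]) - expected[[organ]]),
              4 * se[[organ]])
})

test_that("organs without events show no systematic longitudinal trend", {
  mask <- test_phantom_mask()
  spec <- cohortSpec(n_patients = 50, seed = 17,
                     prevalence = c(bowel = 0, lung = 0, thyroid = 0))
  coh <- simulateCohort(spec, model = uptakeModel(), mask = mask)
  pr <- coh@profiles[coh@profiles$percentile == 95 &
                       coh@profiles$organ == "bowel", ]
  slopes <- vapply(split(pr, pr$patient_id), function(df) {
    if (nrow(df) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(suv_gml ~ scan_day, df))[2])
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  # mean slope across patients indistinguishable from zero
  tt <- stats::t.test(slopes)
  expect_gt(tt$p.value, 0.01)
})

test_that("truth table is consistent with the generated images", {
  mask <- test_phantom_mask()
  spec <- cohortSpec(n_patients = 8, seed = 23,
                     prevalence = c(bowel = 0.8, lung = 0, thyroid = 0.8),
                     onset_range = c(20, 60), k_range = c(2.5, 3.5))
  coh <- simulateCohort(spec, model = uptakeModel(), mask = mask)
  expect_gt(nrow(coh@truth), 0)
  for (i in seq_len(nrow(coh@truth))) {
    ev <- coh@truth[i, ]
    pct <- if (ev$pattern == "diffuse") 75 else 95
    pr <- coh@profiles[coh@profiles$patient_id == ev$patient_id &
                         coh@profiles$organ == ev$organ &
                         coh@profiles$percentile == pct, ]
    pre <- pr$suv_gml[pr$scan_day < ev$onset_day]
    post <- pr$suv_gml[pr$scan_day > ev$onset_day + 30]
    if (length(pre) && length(post))
      expect_gt(max(post), max(pre))
  }
})

test_that("cohorts can be written to disk and reread", {
  mask <- test_phantom_mask()
  spec <- cohortSpec(n_patients = 3, seed = 31,
                     prevalence = c(bowel = 1, lung = 0, thyroid = 0))
  coh <- simulateCohort(spec, model = uptakeModel(), mask = mask)
  dir <- file.path(tempdir(), "cohtest")
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "organ_mask.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$patient_id, coh@truth$patient_id)
  p1 <- list.files(file.path(dir, "P001"), full.names = TRUE)
  expect_gte(length(p1), 2)
  vol <- readSUVVolume(p1[1])
  mk <- readOrganMask(file.path(dir, "organ_mask.nii.gz"))
  expect_true(sameGrid(voxelGrid(vol), voxelGrid(mk), tol = 1e-3))
  # profiles recomputed from disk match the stored profiles
  day <- as.integer(sub(".*day([+-]\\d+)\\.nii\\.gz", "\\1", p1[1]))
  rows <- quantifyScan(suvVolume(voxels(vol), voxelGrid(mk),
                                 scanMeta("P001", day)), mk)
  stored <- coh@profiles[coh@profiles$patient_id == "P001" &
                           coh@profiles$scan_day == day, ]
  expect_equal(rows$suv_gml, stored$suv_gml, tolerance = 1e-5)
  unlink(dir, recursive = TRUE)
})
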