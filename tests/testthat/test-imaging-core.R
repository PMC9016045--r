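test_that("SUV normalization applies weight/dose scaling and preserves zeros", {
  g <- imageGrid(c(3, 3, 3), spacing = 2)
  act <- array(5000, c(3, 3, 3))
  act[1, 1, 1] <- 0
  av <- activityVolume(act, g)

  suv <- computeSUV(av, scanMeta("p", 0, 70000, 3.5e8,
                                 suv_precomputed = FALSE))
  expect_equal(voxels(suv)[2, 2, 2], 1.0)
  expect_equal(voxels(suv)[1, 1, 1], 0)

  suv2 <- computeSUV(activityVolume(array(10000, c(3, 3, 3)), g),
                     scanMeta("p", 0, 80000, 4.0e8, suv_precomputed = FALSE))
  expect_equal(voxels(suv2)[1, 1, 1], 2.0)
})

test_that("SUV is linear in activity and inversely linear in dose", {
  g <- imageGrid(c(4, 4, 4))
  set.seed(11)
  act <- array(runif(64, 0, 9000), c(4, 4, 4))
  base <- computeSUV(activityVolume(act, g),
                     scanMeta("p", 0, 65000, 3e8, suv_precomputed = FALSE))
  x3 <- computeSUV(activityVolume(act * 3, g),
                   scanMeta("p", 0, 65000, 3e8, suv_precomputed = FALSE))
  d3 <- computeSUV(activityVolume(act, g),
                   scanMeta("p", 0, 65000, 9e8, suv_precomputed = FALSE))
  expect_equal(voxels(x3), voxels(base) * 3)
  expect_equal(voxels(d3), voxels(base) / 3)
})

test_that("nonpositive weight or dose is an invalid-metadata error", {
  g <- imageGrid(c(2, 2, 2))
  av <- activityVolume(array(1, c(2, 2, 2)), g)
  expect_error(computeSUV(av, scanMeta("p", 0)), "invalid metadata")
  # the metadata class itself refuses nonpositive values
  expect_error(scanMeta("p", 0, -1, 3e8, suv_precomputed = FALSE),
               "weight_g")
  expect_error(scanMeta("p", 0, 7e4, 0, suv_precomputed = FALSE), "dose_Bq")
})

test_that("mask resampling: identity, idempotence, downsampling, emptiness", {
  src <- imageGrid(c(4, 4, 4), spacing = 1)
  lab <- array(1L, c(4, 4, 4))
  mask <- organMask(lab, src)

  expect_identical(maskArray(resampleMaskTo(mask, src)), maskArray(mask))

  tgt <- imageGrid(c(2, 2, 2), spacing = 2)
  down <- resampleMaskTo(mask, tgt)
  expect_true(all(maskArray(down) == 1L))

  # nearest-neighbour lookup oracle: each target centre maps to its nearest
  # source voxel
  src2 <- imageGrid(c(4, 4, 4), spacing = 1)
  lab2 <- array(sample(c(0L, 1L, 2L), 64, replace = TRUE), c(4, 4, 4))
  m2 <- organMask(lab2, src2)
  t2 <- imageGrid(c(3, 3, 3), spacing = 1.4, origin = c(0.2, 0.2, 0.2))
  r2 <- resampleMaskTo(m2, t2)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    w <- c(0.2, 0.2, 0.2) + (c(i, j, k) - 1) * 1.4
    idx <- round(w / 1) + 1
    expect_identical(maskArray(r2)[i, j, k], lab2[idx[1], idx[2], idx[3]])
  }
  expect_true(all(unique(as.vector(maskArray(r2))) %in%
                    unique(as.vector(lab2))))

  empty <- organMask(array(0L, c(4, 4, 4)), src)
  expect_true(all(maskArray(resampleMaskTo(empty, tgt)) == 0L))

  far <- imageGrid(c(2, 2, 2), spacing = 2, origin = c(500, 500, 500))
  expect_error(resampleMaskTo(mask, far), "disjoint")
})

test_that("masked-value extraction returns exactly the labelled voxels", {
  mask <- toy_mask()
  g <- voxelGrid(mask)

  uniform <- suvVolume(array(2, g@dims), g)
  vals <- extractMaskedValues(uniform, mask, "bowel")
  expect_equal(length(vals), sum(maskArray(mask) == 1L))
  expect_true(all(vals == 2))

  # checkerboard: multiset of values at known voxels
  vox <- array(1, g@dims)
  vox[(slice.index(vox, 1) + slice.index(vox, 2) +
         slice.index(vox, 3)) %% 2 == 0] <- 3
  cb <- suvVolume(vox, g)
  got <- extractMaskedValues(cb, mask, "thyroid")
  expect_equal(sort(got), sort(vox[maskArray(mask) == 3L]))

  # single voxel
  lab <- array(0L, g@dims); lab[3, 5, 7] <- 2L
  one <- organMask(lab, g)
  vox2 <- array(runif(prod(g@dims)), g@dims)
  expect_equal(extractMaskedValues(suvVolume(vox2, g), one, "lung"),
               vox2[3, 5, 7])

  expect_error(extractMaskedValues(uniform, one, "bowel"), "empty organ")
  other <- suvVolume(array(1, c(8, 8, 8)), imageGrid(c(8, 8, 8), spacing = 3))
  expect_error(extractMaskedValues(other, mask, "bowel"), "different grids")
})

test_that("organ cropping preserves the organ's voxels and world coordinates", {
  mask <- test_phantom_mask()
  crop <- cropOrganMask(mask, "thyroid")
  expect_equal(sum(maskArray(crop) == 3L), sum(maskArray(mask) == 3L))
  expect_true(all(maskArray(crop) %in% c(0L, 3L)))
  # world positions of thyroid voxels must be unchanged
  world <- function(m, code) {
    co <- arrayInd(which(maskArray(m) == code), voxelGrid(m)@dims)
    w <- sweep(sweep(co - 1, 2, voxelGrid(m)@spacing, "*"), 2,
               voxelGrid(m)@origin, "+")
    w[order(w[, 1], w[, 2], w[, 3]), ]
  }
  expect_equal(world(crop, 3L), world(mask, 3L))
})

test_that("NIfTI round-trip preserves voxels, spacing and origin", {
  g <- imageGrid(c(6, 5, 4), spacing = c(2, 2, 3), origin = c(10, -4, 0))
  set.seed(5)
  vol <- suvVolume(array(runif(120, 0, 5), c(6, 5, 4)), g,
                   scanMeta("p9", 42))
  f <- tempfile(fileext = ".nii.gz")
  writeSUVVolume(vol, f)
  back <- readSUVVolume(f, scanInfo(vol))
  expect_equal(voxels(back), voxels(vol), tolerance = 1e-6)
  expect_true(sameGrid(voxelGrid(back), g, tol = 1e-4))

  lab <- array(sample(0:3, 120, replace = TRUE), c(6, 5, 4))
  mf <- tempfile(fileext = ".nii.gz")
  writeOrganMask(organMask(lab, g), mf)
  mback <- readOrganMask(mf)
  expect_identical(maskArray(mback), array(as.integer(lab), dim(lab)))

  tab <- data.frame(patient_id = "p9", scan_day = 42, weight_g = 7e4,
                    dose_Bq = 3.5e8, suv_precomputed = 0L)
  tf <- tempfile(fileext = ".csv")
  writeScanTable(tab, tf)
  metas <- readScanTable(tf)
  expect_equal(metas[["p9:42"]]@weight_g, 7e4)
  expect_false(metas[["p9:42"]]@suv_precomputed)
  unlink(c(f, mf, tf))
})
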