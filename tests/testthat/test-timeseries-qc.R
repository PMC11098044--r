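# Parcel extraction, outlier flagging, dataset rejection, nuisance
# regression.

make_phantom <- function(nT = 10, seed = 1) {
  set.seed(seed)
  atlas <- array(0L, c(4, 4, 2))
  atlas[1:2, , ] <- 1L
  atlas[3:4, , ] <- 2L
  bold <- array(rnorm(4 * 4 * 2 * nT), c(4, 4, 2, nT))
  gm <- array(runif(4 * 4 * 2), c(4, 4, 2))
  list(atlas = atlas, bold = bold, gm = gm)
}

test_that("uniform grey-matter weights reduce to the plain parcel mean", {
  ph <- make_phantom()
  ts <- extractRegionalTimeSeries(ph$bold, ph$atlas, NULL)
  expected <- sapply(1:2, function(lab) {
    idx <- which(as.vector(ph$atlas) == lab)
    colMeans(matrix(ph$bold, 32, 10)[idx, ])
  })
  expect_equal(unname(tsMatrix(ts)), expected)
  expect_equal(regionLabels(ts), c("parcel_1", "parcel_2"))
})

test_that("grey-matter weighting is the probability-weighted voxel mean", {
  # 2-voxel parcel, p = (0.2, 0.8), signals (10, 20) -> 18
  atlas <- array(c(1L, 1L), c(2, 1, 1))
  gm <- array(c(0.2, 0.8), c(2, 1, 1))
  bold <- array(c(10, 20), c(2, 1, 1, 1))
  ts <- extractRegionalTimeSeries(bold, atlas, gm)
  expect_equal(unname(tsMatrix(ts)[1, 1]), 18)

  # a zero-probability voxel has no influence
  gm0 <- array(c(0, 1), c(2, 1, 1))
  ts0 <- extractRegionalTimeSeries(bold, atlas, gm0)
  expect_equal(unname(tsMatrix(ts0)[1, 1]), 20)
})

test_that("zero-probability parcels yield NA columns with a warning, bad grids error", {
  atlas <- array(c(1L, 2L), c(2, 1, 1))
  gm <- array(c(1, 0), c(2, 1, 1))
  bold <- array(c(10, 20), c(2, 1, 1, 1))
  expect_warning(ts <- extractRegionalTimeSeries(bold, atlas, gm), "zero total")
  expect_true(all(is.na(tsMatrix(ts)[, 2])))

  expect_error(
    extractRegionalTimeSeries(bold, array(1L, c(3, 1, 1)), NULL),
    "grids differ"
  )
  expect_error(
    extractRegionalTimeSeries(bold, array(0L, c(2, 1, 1)), NULL),
    "no non-background"
  )
})

test_that("phantom NIfTI files round-trip through extraction", {
  dir <- withr::local_tempdir()
  files <- makeFixtures(seed = 3, outdir = dir)
  ts_file <- extractRegionalTimeSeries(
    file.path(dir, "phantom_bold.nii.gz"),
    file.path(dir, "phantom_atlas.nii.gz"),
    file.path(dir, "phantom_gm.nii.gz")
  )
  # same arrays in memory give identical series
  atlas <- array(0L, c(4, 4, 2))
  atlas[1:2, , ] <- 1L
  atlas[3:4, , ] <- 2L
  gm <- array(0.8, c(4, 4, 2))
  bold <- hdinet:::with_seed(3, array(rnorm(320), c(4, 4, 2, 10)))
  ts_mem <- extractRegionalTimeSeries(bold, atlas, gm)
  expect_equal(tsMatrix(ts_file), tsMatrix(ts_mem), tolerance = 1e-6)
})

test_that("outlier flagging applies the 5 mm and 3 SD inter-volume rules", {
  zero <- matrix(0, 100, 6)
  expect_equal(sum(flagOutlierVolumes(zero, rep(1, 100))), 0)

  # a single 6 mm translation step flags exactly that volume
  m <- zero
  m[50:100, 1] <- 6
  fl <- flagOutlierVolumes(m, NULL)
  expect_equal(which(fl), 50L)

  # signal spike of 4 SD flags, 2 SD does not
  set.seed(1)
  base <- rnorm(200)
  s4 <- base
  s4[120] <- s4[119] + 4 * sd(s4)
  expect_true(flagOutlierVolumes(matrix(0, 200, 6), s4)[120])
  s2 <- base
  s2[120] <- s2[119] + 2 * sd(s2)
  expect_false(flagOutlierVolumes(matrix(0, 200, 6), s2)[120])
})

test_that("flagging ignores constant offsets of the global signal and spares volume 1", {
  set.seed(2)
  m <- matrix(rnorm(300, sd = 0.01), 50, 6)
  gs <- rnorm(50)
  f1 <- flagOutlierVolumes(m, gs)
  f2 <- flagOutlierVolumes(m, gs + 1000)
  expect_identical(as.logical(f1), as.logical(f2))
  expect_false(f1[1])
  expect_error(flagOutlierVolumes(matrix(0, 1, 6), 1), "at least 2")
})

test_that("rejection is strict at the 10% boundary", {
  expect_false(rejectDataset(rep(c(TRUE, FALSE), c(11, 89)))) # 11% -> reject
  expect_true(rejectDataset(rep(c(TRUE, FALSE), c(10, 90)))) # 10% -> keep
  expect_true(rejectDataset(rep(FALSE, 100)))
})

test_that("motion spikes at >10% of volumes lead to dataset rejection downstream", {
  art <- simulateMotionArtifacts(100, spikeTimes = seq(5, 95, by = 9), seed = 1)
  mask <- flagOutlierVolumes(art$motion, NULL)
  expect_gte(sum(mask), 11)
  expect_false(rejectDataset(mask))
})

test_that("nuisance regression removes motion, zeroes outliers, keeps orthogonal signal", {
  set.seed(3)
  n <- 400
  motion <- matrix(rnorm(n * 6), n, 6)
  # region equal to a motion column -> all-zero residual
  ts <- new("RegionalTimeSeries",
    data = cbind(motion[, 2], rnorm(n)),
    regionLabels = c("a", "b"), samplingInterval = 2
  )
  clean <- regressNuisance(ts, motion)
  expect_lt(max(abs(tsMatrix(clean)[, 1])), 1e-10)

  # injected-noise recovery: signal = 2*motion1 + noise
  noise <- rnorm(n)
  ts2 <- new("RegionalTimeSeries",
    data = cbind(2 * motion[, 1] + noise),
    regionLabels = "a", samplingInterval = 2
  )
  res <- tsMatrix(regressNuisance(ts2, motion))[, 1]
  expect_gt(cor(res, noise), 0.99)

  # flagged volumes come back exactly 0
  mask <- rep(FALSE, n)
  mask[c(10, 20)] <- TRUE
  res3 <- tsMatrix(regressNuisance(ts2, motion, mask))
  expect_identical(res3[c(10, 20), 1], c(0, 0))

  # all volumes flagged -> rank-deficient design
  expect_error(regressNuisance(ts2, motion, rep(TRUE, n)), "rank-deficient")
})

test_that("nuisance regression is an idempotent projection with orthogonal residuals", {
  set.seed(4)
  n <- 60
  motion <- matrix(rnorm(n * 6), n, 6)
  mask <- rep(FALSE, n)
  mask[15] <- TRUE
  ts <- new("RegionalTimeSeries",
    data = matrix(rnorm(n * 3), n, 3),
    regionLabels = letters[1:3], samplingInterval = 2
  )
  once <- regressNuisance(ts, motion, mask)
  twice <- regressNuisance(once, motion, mask)
  expect_equal(tsMatrix(once), tsMatrix(twice), tolerance = 1e-10)

  design <- cbind(1, motion)
  std <- apply(design, 2, function(c) c / sqrt(sum(c^2)))
  ip <- crossprod(std, tsMatrix(once))
  expect_lt(max(abs(ip)), 1e-8)
})
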