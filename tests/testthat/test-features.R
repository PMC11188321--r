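# discretization, shape and first-order features

test_that("equal-width discretization follows the binning rule", {
  v <- petVolume(array(c(1, 2, 3, 4, rep(1, 4)), c(2, 2, 2)), spacing = 4)
  m <- array(FALSE, c(2, 2, 2)); m[1:4] <- TRUE
  dv <- discretizeVOI(v, lesionMask(m, 4), nBins = 2)
  expect_equal(dv@levels[1:4], c(1L, 1L, 2L, 2L))
  expect_true(all(is.na(dv@levels[5:8])))
})

test_that("levels never exceed Ng and histograms match a direct binning oracle", {
  set.seed(3)
  v <- petVolume(array(runif(216, 2, 9), c(6, 6, 6)), spacing = 4)
  m <- lesionMask(array(runif(216) < 0.7, c(6, 6, 6)), 4)
  for (ng in c(8, 64)) {
    dv <- discretizeVOI(v, m, nBins = ng)
    lev <- dv@levels[!is.na(dv@levels)]
    expect_lte(max(lev), ng)
    expect_gte(min(lev), 1)
    # oracle: cut() with the same equal-width edges
    x <- voxelData(v)[voxelData(m)]
    edges <- seq(min(x), max(x), length.out = ng + 1)
    oracle <- as.integer(cut(x, breaks = edges, include.lowest = TRUE))
    expect_equal(tabulate(lev, ng), tabulate(oracle, ng))
  }
  vc <- petVolume(array(5, c(4, 4, 4)), spacing = 4)
  mc <- lesionMask(array(TRUE, c(4, 4, 4)), 4)
  expect_warning(dvc <- discretizeVOI(vc, mc, 8), "constant VOI")
  expect_true(all(dvc@levels == 1L))
})

test_that("a large digital sphere is recognised as (near-)spherical", {
  m <- digitalSphere(12, spacing = c(1, 1, 1))
  f <- shapeFeatures(m)
  expect_lt(abs(f[["shape.QCFX.sphericity"]] - 1), 0.02)
  # algebraic identity: spherical disproportion = 1 / sphericity
  expect_lt(abs(f[["shape.KRCK.spherical_disproportion"]] -
                1 / f[["shape.QCFX.sphericity"]]), 1e-9)
  expect_lt(abs(f[["shape.25C7.asphericity"]] -
                (1 / f[["shape.QCFX.sphericity"]] - 1)), 1e-9)
  # compactness identities
  expect_lt(abs(f[["shape.BQWJ.compactness2"]] -
                f[["shape.QCFX.sphericity"]]^3), 1e-9)
  # max 3D diameter close to the true diameter (24 mm)
  expect_lt(abs(f[["shape.L0JK.max_3d_diameter"]] / 24 - 1), 0.1)
})

test_that("digital cube surface and volume approximate the analytic values", {
  m <- array(FALSE, c(16, 16, 16))
  m[4:13, 4:13, 4:13] <- TRUE  # 10 voxels at 4 mm = 40 mm edge
  f <- shapeFeatures(lesionMask(m, spacing = 4))
  expect_lt(abs(f[["shape.C0JK.surface_area"]] * 100 / 9600 - 1), 0.05)
  expect_lt(abs(f[["shape.RNU0.volume"]] * 1000 / 64000 - 1), 0.05)
  expect_equal(f[["shape.YEKZ.approx_volume"]], 64)  # 1000 voxels x 0.064
})

test_that("single-voxel masks yield finite shape values", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  v <- petVolume(array(2, c(5, 5, 5)), spacing = 4)
  f <- shapeFeatures(lesionMask(m, 4), volume = v)
  expect_true(all(is.finite(f)))
  expect_gt(f[["shape.RNU0.volume"]], 0)
})

test_that("intensity-weighted shape features respond to the SUV pattern", {
  p <- spherePhantom(radiusMM = 20, texture = "radial-gradient", seed = 5)
  f <- shapeFeatures(p$masks[[1]], volume = p$volume)
  # symmetric gradient: centre of mass barely moves
  expect_lt(f[["shape.KLMA.com_shift"]], 1)
  mm <- metabolicMetrics(p$volume, p$masks[[1]])
  expect_lt(abs(f[["shape.99N0.integrated_intensity"]] -
                mm$suvmean * f[["shape.RNU0.volume"]]), 1e-9)
})

test_that("constant VOI first-order features follow the stated conventions", {
  v <- petVolume(array(5, c(4, 4, 4)), spacing = 4)
  m <- lesionMask(array(TRUE, c(4, 4, 4)), 4)
  dv <- suppressWarnings(discretizeVOI(v, m, 8))
  f <- intensityFeatures(v, m, dv)
  expect_equal(f[["firstorder.Q4LE.mean"]], 5)
  expect_equal(f[["firstorder.ECT3.variance"]], 0)
  expect_equal(f[["firstorder.KE2A.skewness"]], 0)
  expect_equal(f[["firstorder.IPH6.kurtosis"]], 0)
  expect_equal(f[["firstorder.2OJQ.range"]], 0)
  expect_equal(f[["firstorder.0F91.global_intensity_peak"]], 5)
})

test_that("percentiles match an independent percentile routine", {
  v <- petVolume(array(c(1:100, rep(0, 25)), c(5, 5, 5)), spacing = 4)
  m <- array(FALSE, c(5, 5, 5)); m[1:100] <- TRUE
  mk <- lesionMask(m, 4)
  dv <- discretizeVOI(v, mk, 16)
  f <- intensityFeatures(v, mk, dv)
  q <- unname(quantile(1:100, c(0.1, 0.5, 0.9), type = 7))
  expect_equal(f[["firstorder.QG58.p10"]], q[1])
  expect_equal(f[["firstorder.Y12H.1.p50"]], q[2])
  expect_equal(f[["firstorder.8DWT.p90"]], q[3])
  expect_equal(f[["firstorder.Y12H.median"]], median(1:100))
  expect_equal(f[["firstorder.SALO.iqr"]],
               unname(diff(quantile(1:100, c(0.25, 0.75), type = 7))))
})

test_that("uniform histograms attain maximum entropy and minimum uniformity", {
  ng <- 8
  vals <- rep(seq(1, 8, length.out = ng), each = 8)  # 8 voxels per level
  v <- petVolume(array(c(vals, rep(0, 64)), c(8, 4, 4)), spacing = 4)
  m <- array(FALSE, c(8, 4, 4)); m[1:64] <- TRUE
  mk <- lesionMask(m, 4)
  dv <- discretizeVOI(v, mk, ng)
  f <- intensityFeatures(v, mk, dv)
  expect_equal(f[["firstorder.TLU2.ih_entropy"]], log2(ng))
  expect_equal(f[["firstorder.BJ5W.uniformity"]], 1 / ng)
})

test_that("histogram gradient features follow the finite-difference definition", {
  lev <- array(NA_integer_, c(4, 4, 4))
  lev[1:40] <- rep(1:4, c(4, 16, 14, 6))
  dv <- asDVOI(lev, 4)
  vals <- as.numeric(lev); vals[is.na(vals)] <- 0
  v <- petVolume(array(vals, c(4, 4, 4)), spacing = 4)
  mk <- lesionMask(!is.na(lev), 4)
  f <- intensityFeatures(v, mk, dv)
  cnts <- c(4, 16, 14, 6)
  g <- c(cnts[2] - cnts[1], (cnts[3] - cnts[1]) / 2,
         (cnts[4] - cnts[2]) / 2, cnts[4] - cnts[3])
  expect_equal(f[["firstorder.12CE.max_hist_gradient"]], max(g))
  expect_equal(f[["firstorder.8E6O.max_hist_gradient_grey_level"]],
               which.max(g))
  expect_equal(f[["firstorder.VQB3.min_hist_gradient"]], min(g))
  expect_equal(f[["firstorder.RHQZ.min_hist_gradient_grey_level"]],
               which.min(g))
})
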