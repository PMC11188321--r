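# GLCM / GLRLM / NGTDM / GLSZM against brute-force oracles

test_that("constant VOI GLCM features take their degenerate conventions", {
  lev <- array(1L, c(3, 3, 3))
  f <- glcmFeatures(asDVOI(lev, 4))
  expect_equal(f[["glcm.GYBY.joint_maximum"]], 1)
  expect_equal(f[["glcm.ACUI.contrast"]], 0)
  expect_equal(f[["glcm.NI2N.correlation"]], 0)
  expect_equal(f[["glcm.8ZQL.angular_second_moment"]], 1)
})

test_that("GLCM features equal exhaustive pair enumeration on a hand grid", {
  lev <- array(NA_integer_, c(4, 4, 1))
  lev[, , 1] <- matrix(c(1, 2, 2, 3,
                         1, 1, 3, 3,
                         4, 2, 2, 1,
                         4, 4, 1, 2), 4, byrow = TRUE)
  dv <- asDVOI(lev, 4)
  mats <- glcmMatrices(dv)
  omats <- oracleGLCM(lev, 4)
  for (i in seq_along(mats)) {
    if (is.null(omats[[i]])) expect_null(mats[[i]])
    else expect_equal(mats[[i]], omats[[i]], tolerance = 1e-12,
                      ignore_attr = TRUE)
  }
  keep <- !vapply(omats, is.null, logical(1))
  of <- rowMeans(vapply(omats[keep], oracleGLCMFeatures, numeric(23)))
  expect_equal(unname(glcmFeatures(dv)), unname(of), tolerance = 1e-9)
})

test_that("averaged GLCM features are invariant under 90-degree rotations", {
  set.seed(8)
  lev <- array(sample.int(3, 64, TRUE), c(4, 4, 4))
  lev[runif(64) < 0.2] <- NA_integer_
  rot <- aperm(lev[, 4:1, ], c(2, 1, 3))  # 90-degree rotation in x-y
  f1 <- glcmFeatures(asDVOI(lev, 3))
  f2 <- glcmFeatures(asDVOI(rot, 3))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("run-length features on constructed lines match the definitions", {
  # constant 1 x 1 x N line: one run of length N in the line direction
  N <- 6
  lev <- array(NA_integer_, c(1, 1, N))
  lev[1, 1, ] <- 1L
  f <- glrlmFeatures(asDVOI(lev, 2))
  # 12 off-axis directions see N runs of length 1, the axis sees 1 run
  expect_equal(unname(f[["glrlm.9ZK5.run_percentage"]]),
               (12 * 1 + 1 / N) / 13)
  # alternating levels: every run has length 1 in all directions
  lev[1, 1, ] <- rep(c(1L, 2L), 3)
  fa <- glrlmFeatures(asDVOI(lev, 2))
  expect_equal(unname(fa[["glrlm.22OV.short_runs_emphasis"]]), 1)
  expect_equal(unname(fa[["glrlm.9ZK5.run_percentage"]]), 1)
})

test_that("GLRLM matrices and features equal the run-walking oracle", {
  set.seed(9)
  lev <- array(sample.int(3, 125, TRUE), c(5, 5, 5))
  lev[runif(125) < 0.25] <- NA_integer_
  dv <- asDVOI(lev, 3)
  mats <- glrlmMatrices(dv)
  om <- oracleGLRLM(lev, 3)
  for (i in seq_along(mats))
    expect_equal(unname(mats[[i]]), unname(om[[i]]))
  nVox <- sum(!is.na(lev))
  of <- rowMeans(vapply(om, petrad:::.glrlmFeaturesOne, numeric(11),
                        nVox = nVox))
  expect_equal(unname(glrlmFeatures(dv)), unname(of), tolerance = 1e-12)
})

test_that("NGTDM of a constant VOI is capped-coarse and contrast-free", {
  lev <- array(1L, c(3, 3, 3))
  f <- ngtdmFeatures(asDVOI(lev, 3))
  expect_equal(unname(f[["ngtdm.QCDE.coarseness"]]), 1e6)
  expect_equal(unname(f[["ngtdm.65HE.contrast"]]), 0)
})

test_that("NGTDM matches the explicit neighbourhood oracle on a checkerboard", {
  g <- expand.grid(1:4, 1:4, 1:4)
  lev <- array(1L + (g[, 1] + g[, 2] + g[, 3]) %% 2L, c(4, 4, 4))
  dv <- asDVOI(lev, 2)
  tb <- ngtdmTable(dv)
  otb <- oracleNGTDM(lev, 2)
  expect_equal(tb$s, otb$s)
  expect_equal(tb$n, otb$n)
  # hand-computed contrast for the two-level checkerboard:
  # p1 = p2 = 1/2 and the oracle s-table gives the average difference
  N <- 64
  f <- ngtdmFeatures(dv)
  expected <- (2 * 0.5 * 0.5 * 1) / (2 * 1) * sum(otb$s) / N
  expect_equal(unname(f[["ngtdm.65HE.contrast"]]), expected)
})

test_that("random VOIs give identical NGTDM features via the oracle table", {
  set.seed(10)
  lev <- array(sample.int(4, 125, TRUE), c(5, 5, 5))
  lev[runif(125) < 0.3] <- NA_integer_
  tb <- ngtdmTable(asDVOI(lev, 4))
  otb <- oracleNGTDM(lev, 4)
  expect_equal(tb$s, otb$s, tolerance = 1e-12)
  expect_equal(tb$n, otb$n)
})

test_that("single-voxel VOI yields finite NGTDM features", {
  lev <- array(NA_integer_, c(3, 3, 3)); lev[2, 2, 2] <- 1L
  f <- ngtdmFeatures(asDVOI(lev, 2))
  expect_true(all(is.finite(f)))
})

test_that("GLSZM identities hold on constructed VOIs", {
  # constant VOI of V voxels: single zone, zone percentage 1/V
  lev <- array(1L, c(3, 3, 3))
  f <- glszmFeatures(asDVOI(lev, 2))
  expect_equal(unname(f[["glszm.P30P.zone_percentage"]]), 1 / 27)
  expect_equal(unname(f[["glszm.48P8.large_zone_emphasis"]]), 27^2)
  # isolated voxels of distinct levels: all zones size 1
  lev2 <- array(NA_integer_, c(5, 5, 5))
  lev2[1, 1, 1] <- 1L; lev2[5, 5, 5] <- 2L; lev2[1, 5, 3] <- 3L
  f2 <- glszmFeatures(asDVOI(lev2, 3))
  expect_equal(unname(f2[["glszm.5QRC.small_zone_emphasis"]]), 1)
  expect_equal(unname(f2[["glszm.P30P.zone_percentage"]]), 1)
})

test_that("GLSZM matches the flood-fill oracle on random VOIs", {
  set.seed(11)
  for (rep in 1:3) {
    lev <- array(sample.int(3, 125, TRUE), c(5, 5, 5))
    lev[runif(125) < 0.3] <- NA_integer_
    M <- glszmMatrix(asDVOI(lev, 3))
    O <- oracleGLSZM(lev, 3)
    O <- O[, seq_len(ncol(M)), drop = FALSE]
    expect_equal(unname(M), unname(O))
  }
})

test_that("every texture family agrees with its oracle across a VOI sweep", {
  set.seed(12)
  for (rep in 1:6) {
    dim <- sample(3:6, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    lev <- array(sample.int(ng, prod(dim), TRUE), dim)
    lev[runif(prod(dim)) < 0.2] <- NA_integer_
    if (all(is.na(lev))) lev[1] <- 1L
    dv <- asDVOI(lev, ng)
    # GLCM
    om <- oracleGLCM(lev, ng)
    keep <- !vapply(om, is.null, logical(1))
    if (any(keep)) {
      of <- rowMeans(vapply(om[keep], oracleGLCMFeatures, numeric(23)))
      expect_equal(unname(glcmFeatures(dv)), unname(of), tolerance = 1e-9)
    }
    # GLRLM
    nVox <- sum(!is.na(lev))
    orl <- oracleGLRLM(lev, ng)
    ofrl <- rowMeans(vapply(orl, petrad:::.glrlmFeaturesOne, numeric(11),
                            nVox = nVox))
    expect_equal(unname(glrlmFeatures(dv)), unname(ofrl), tolerance = 1e-12)
    # NGTDM table
    tb <- ngtdmTable(dv); otb <- oracleNGTDM(lev, ng)
    expect_equal(tb$s, otb$s, tolerance = 1e-12)
    expect_equal(tb$n, otb$n)
    # GLSZM
    M <- glszmMatrix(dv); O <- oracleGLSZM(lev, ng)
    expect_equal(unname(M), unname(O[, seq_len(ncol(M)), drop = FALSE]))
  }
})

test_that("GLCM matrices are normalized per direction before averaging", {
  set.seed(13)
  lev <- array(sample.int(3, 64, TRUE), c(4, 4, 4))
  mats <- glcmMatrices(asDVOI(lev, 3))
  for (m in mats) if (!is.null(m)) expect_equal(sum(m), 1)
})
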