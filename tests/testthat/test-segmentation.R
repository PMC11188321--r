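test_that("threshold rule includes exactly the voxels at >= 41% of SUVmax", {
  # region max SUV 10 -> inclusion threshold 4.1
  v <- array(1, c(12, 12, 12))
  v[4:6, 4:6, 4:6] <- 10
  v[7, 4, 4] <- 4.1   # exactly at threshold, adjacent -> included
  v[8, 4, 4] <- 4.0   # below threshold -> excluded
  vol <- petVolume(v, spacing = 4)
  m <- segmentLesion(vol, seed = c(5, 5, 5))
  expect_true(voxelData(m)[7, 4, 4])
  expect_false(voxelData(m)[8, 4, 4])
  expect_equal(sum(voxelData(m)), 27 + 1)
})

test_that("a uniform region is segmented in its entirety (v >= 0.41 v)", {
  vol <- petVolume(array(5, c(8, 8, 8)), spacing = 4)
  m <- segmentLesion(vol, seed = c(4, 4, 4))
  expect_equal(sum(voxelData(m)), 8^3)
})

test_that("a cold lesion below 41% of the hot lesion's SUVmax is excluded", {
  p <- makePhantom(phantomSpec(noiseSD = 0, lesions = list(
    lesionSpec(center = c(64, 128, 128), radii = 20, peak = 10),
    lesionSpec(center = c(192, 128, 128), radii = 20, peak = 3))))
  m <- segmentLesion(p$volume, seed = list(lo = c(1, 1, 1),
                                           hi = c(64, 64, 64)))
  expect_true(all(voxelData(m)[voxelData(p$masks[[1]])]))
  expect_false(any(voxelData(m) & voxelData(p$masks[[2]])))
})

test_that("segmentation recovers the uniform high-contrast ground truth (Dice >= 0.9)", {
  p <- spherePhantom(radiusMM = 20, peak = 10, background = 1,
                     noiseSD = 0.05, seed = 9)
  m <- segmentLesion(p$volume, seed = c(32, 32, 32))
  truth <- voxelData(p$masks[[1]])
  dice <- 2 * sum(voxelData(m) & truth) / (sum(voxelData(m)) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("an all-background search region raises an empty-mask error", {
  v <- array(1, c(12, 12, 12)); v[6, 6, 6] <- 10
  vol <- petVolume(v, spacing = 4)
  expect_error(segmentLesion(vol, seed = list(lo = c(1, 1, 1),
                                              hi = c(3, 3, 3)),
                             global = TRUE),
               "empty mask|threshold")
})

test_that("raising the threshold fraction never enlarges the mask", {
  p <- spherePhantom(radiusMM = 20, texture = "radial-gradient", seed = 4)
  sizes <- vapply(c(0.41, 0.5, 0.6, 0.8), function(fr)
    sum(voxelData(segmentLesion(p$volume, seed = c(32, 32, 32),
                                fraction = fr))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("MTV filter removes lesions strictly below the cutoff", {
  vol <- petVolume(array(1, c(20, 20, 20)), spacing = 4)  # voxel = 0.064 cm3
  mk <- function(nvox) {
    m <- array(FALSE, c(20, 20, 20)); m[seq_len(nvox)] <- TRUE
    lesionMask(m, spacing = 4)
  }
  # 9.9 cm^3 < 10 removed; >= 10 retained
  small <- mk(154)          # 9.856 cm^3
  boundary <- mk(157)       # 10.048 cm^3 (>= 10, first size above)
  expect_length(filterLesions(list(small), vol), 0)
  expect_length(filterLesions(list(boundary), vol), 1)
  # exact boundary with unit-mm voxels: 10.0 cm^3 is retained
  vol1 <- petVolume(array(1, c(30, 30, 30)), spacing = c(10, 10, 10))
  m10 <- lesionMask(array(rep(c(TRUE, FALSE), c(10, 27000 - 10)),
                          c(30, 30, 30)), spacing = c(10, 10, 10))
  expect_length(filterLesions(list(m10), vol1), 1)  # 10 x 1 cm^3 exactly
  # 5 / 11 / 80 cm^3 -> 2 survivors, order preserved
  out <- filterLesions(list(mk(78), mk(172), mk(1250)), vol)
  expect_length(out, 2)
  expect_equal(sapply(out, function(m) sum(voxelData(m))), c(172, 1250))
})

test_that("metabolic metrics follow their definitions", {
  # uniform lesion SUV 5 occupying 20 cm^3
  v <- petVolume(array(5, c(20, 20, 20)), spacing = c(10, 10, 10))
  m <- array(FALSE, c(20, 20, 20)); m[seq_len(20)] <- TRUE  # 20 x 1 cm^3
  mm <- metabolicMetrics(v, lesionMask(m, spacing = c(10, 10, 10)))
  expect_equal(mm$suvmax, 5)
  expect_equal(mm$suvmean, 5)
  expect_equal(mm$mtv_cm3, 20)
  expect_equal(mm$tlg, 100)
  # 250 voxels at 4x4x4 mm -> 16 cm^3
  v2 <- petVolume(array(runif(8000, 1, 9), c(20, 20, 20)), spacing = 4)
  m2 <- array(FALSE, c(20, 20, 20)); m2[seq_len(250)] <- TRUE
  mm2 <- metabolicMetrics(v2, lesionMask(m2, spacing = 4))
  expect_equal(mm2$mtv_cm3, 250 * 0.064)
  # TLG identity to 1e-9 relative
  expect_lt(abs(mm2$tlg / (mm2$suvmean * mm2$mtv_cm3) - 1), 1e-9)
  expect_gte(mm2$suvmax, mm2$suvmean)
  expect_error(metabolicMetrics(v2, lesionMask(array(FALSE, c(20, 20, 20)),
                                               spacing = 4)), "empty")
})

test_that("MTV is additive over disjoint masks and patient metrics aggregate", {
  v <- petVolume(array(runif(4096, 1, 5), c(16, 16, 16)), spacing = 4)
  m1 <- array(FALSE, c(16, 16, 16)); m1[1:100] <- TRUE
  m2 <- array(FALSE, c(16, 16, 16)); m2[201:350] <- TRUE
  l1 <- lesionMask(m1, 4, "a"); l2 <- lesionMask(m2, 4, "b")
  mm1 <- metabolicMetrics(v, l1); mm2 <- metabolicMetrics(v, l2)
  u <- lesionMask(m1 | m2, 4)
  mmu <- metabolicMetrics(v, u)
  expect_equal(mmu$mtv_cm3, mm1$mtv_cm3 + mm2$mtv_cm3)
  pm <- patientMetrics(v, list(l1, l2))
  expect_equal(pm$mtv_cm3, mmu$mtv_cm3)
  expect_equal(pm$tlg, mm1$tlg + mm2$tlg)
  expect_equal(pm$suvmax, max(mm1$suvmax, mm2$suvmax))
})
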