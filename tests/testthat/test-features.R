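test_that("discretization follows the fixed-bin-width formula", {
  img <- image_volume(array(c(10, 20, 40, rep(0, 24 - 3)), c(3, 2, 4)))
  v <- array(0L, c(3, 2, 4)); v[1:3] <- 1L
  droi <- discretize(img, label_mask(v), bin_width = 25)
  expect_equal(droi$levels[1:3], c(1L, 1L, 2L))
  expect_equal(droi$ng, 2L)
  expect_equal(droi$bin_origin, 10)

  const <- image_volume(array(42, c(3, 2, 4)))
  d2 <- discretize(const, label_mask(v), 25)
  expect_equal(unique(d2$levels[v == 1L]), 1L)
  expect_equal(d2$ng, 1L)
})

test_that("halving the bin width never decreases the level count", {
  set.seed(31)
  for (rep in 1:20) {
    img <- image_volume(array(rnorm(4^3, 0, 40), c(4, 4, 4)))
    msk <- random_mask(c(4, 4, 4))
    for (w in c(50, 10, 3)) {
      ng1 <- discretize(img, msk, w)$ng
      ng2 <- discretize(img, msk, w / 2)$ng
      expect_gte(ng2, ng1)
    }
  }
})

test_that("first-order features on tiny hand-checked ROIs", {
  img <- image_volume(array(c(1, 2, 3, rep(9, 5)), c(2, 2, 2)))
  v <- array(0L, c(2, 2, 2)); v[1:3] <- 1L
  msk <- label_mask(v)
  f <- first_order_features(img, msk, discretize(img, msk, 1))
  expect_equal(unname(f["Maximum"]), 3)
  expect_equal(unname(f["Median"]), 2)
  expect_equal(unname(f["Range"]), 2)
  expect_equal(unname(f["Mean"]), 2)

  cimg <- image_volume(array(5, c(2, 2, 2)))
  call_ <- label_mask(array(1L, c(2, 2, 2)))
  fc <- first_order_features(cimg, call_, discretize(cimg, call_, 25))
  expect_equal(unname(fc["Variance"]), 0)
  expect_equal(unname(fc["Uniformity"]), 1)
  expect_equal(unname(fc["Entropy"]), 0, tolerance = 1e-12)
  expect_equal(unname(fc["Maximum"]), 5)
  expect_equal(unname(fc["Median"]), 5)
  expect_equal(unname(fc["Skewness"]), 0)
})

test_that("first-order features match a naive reference on random data", {
  set.seed(32)
  vox <- array(rnorm(200, 100, 25), c(10, 5, 4))
  img <- image_volume(vox)
  msk <- label_mask(array(1L, c(10, 5, 4)))
  droi <- discretize(img, msk, 10)
  f <- first_order_features(img, msk, droi)
  x <- as.vector(vox)
  n <- length(x)
  counts <- table(droi$levels)
  p <- as.numeric(counts) / n
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  p10 <- unname(quantile(x, 0.1)); p90 <- unname(quantile(x, 0.9))
  sub <- x[x >= p10 & x <= p90]
  expect_equal(unname(f["Energy"]), sum(x^2))
  expect_equal(unname(f["TotalEnergy"]), sum(x^2) * 1)
  expect_equal(unname(f["Entropy"]), -sum(p * log2(p + ORACLE_EPS)))
  expect_equal(unname(f["10Percentile"]), p10)
  expect_equal(unname(f["90Percentile"]), p90)
  expect_equal(unname(f["InterquartileRange"]),
               unname(quantile(x, .75) - quantile(x, .25)))
  expect_equal(unname(f["MeanAbsoluteDeviation"]), mean(abs(x - mu)))
  expect_equal(unname(f["RobustMeanAbsoluteDeviation"]),
               mean(abs(sub - mean(sub))))
  expect_equal(unname(f["RootMeanSquared"]), sqrt(mean(x^2)))
  expect_equal(unname(f["Skewness"]), (sum((x - mu)^3) / n) / m2^1.5)
  expect_equal(unname(f["Kurtosis"]), (sum((x - mu)^4) / n) / m2^2)
  expect_equal(unname(f["Variance"]), m2)
  expect_equal(unname(f["Uniformity"]), sum(p^2))
})

test_that("shape features of an axis-aligned cube match analytic values", {
  v <- array(0L, c(14, 14, 14)); v[3:12, 3:12, 3:12] <- 1L
  f <- shape_features(label_mask(v))
  expect_equal(unname(f["VoxelVolume"]), 1000)
  # the mollified mesh rounds edges and corners: area and volume sit below
  # the analytic solid, within the documented 20% / 10% tolerances
  expect_lt(abs(f["SurfaceArea"] - 600), 0.20 * 600)
  expect_lt(abs(f["MeshVolume"] - 1000), 0.10 * 1000)
  expect_equal(unname(f["Maximum3DDiameter"]), 9 * sqrt(3))
  expect_equal(unname(f["Maximum2DDiameterSlice"]), 9 * sqrt(2))
  expect_lte(f["Sphericity"], 1)
  expect_equal(unname(f["Elongation"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["Flatness"]), 1, tolerance = 1e-9)
})

test_that("sphericity approaches 1 for a large rasterized ball", {
  n <- 41
  x <- (1:n) - (n + 1) / 2
  r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  ball <- label_mask(array(as.integer(r2 <= 18^2), c(n, n, n)))
  f <- shape_features(ball)
  expect_gt(f["Sphericity"], 0.97)
  expect_lte(f["Sphericity"], 1)
  # anisotropic spacing: physical quantities respect mm units
  slab <- shape_features(label_mask(array(1L, c(4, 4, 4)), spacing = c(1, 1, 3)))
  expect_equal(unname(slab["VoxelVolume"]), 4 * 4 * 4 * 3)
  expect_gt(slab["MajorAxisLength"], slab["LeastAxisLength"])
  # degenerate single-voxel mask stays finite everywhere
  v1 <- array(0L, c(5, 5, 5)); v1[3, 3, 3] <- 1L
  f1 <- shape_features(label_mask(v1))
  expect_true(all(is.finite(f1)))
  expect_equal(unname(f1["VoxelVolume"]), 1)
  expect_equal(unname(f1["Maximum3DDiameter"]), 0)
})

test_that("maximum 3-D diameter equals the brute-force pairwise maximum", {
  set.seed(33)
  for (rep in 1:5) {
    msk <- random_mask(c(9, 10, 11), spacing = c(1, 1.5, 2), p = 0.2)
    pts <- oracle_boundary_coords(msk)
    d <- as.matrix(dist(pts))
    expect_equal(unname(shape_features(msk)["Maximum3DDiameter"]), max(d))
  }
})

test_that("GLCM features on a hand-enumerable 1x1x4 ROI match the oracle", {
  lv <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  droi <- droi_from_levels(lv)
  f <- glcm_features(droi)
  expect_equal(f, oracle_glcm_features(lv, 2), tolerance = 1e-12)
  # the only direction with pairs is along z: pairs (1,1),(1,2),(2,2)
  # symmetrized: P = [[2,1],[1,2]]/6
  expect_equal(unname(f["MaximumProbability"]), 2 / 6)
  expect_equal(unname(f["Contrast"]), 2 / 6)
})

test_that("GLCM degenerate conventions for a constant ROI", {
  lv <- array(1L, c(3, 3, 3))
  f <- glcm_features(droi_from_levels(lv))
  expect_equal(unname(f["ClusterShade"]), 0)
  expect_equal(unname(f["ClusterProminence"]), 0)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["MCC"]), 1)
  expect_equal(unname(f["Correlation"]), 1)
  # single voxel
  lv1 <- array(0L, c(2, 2, 2)); lv1[1] <- 1L
  f1 <- glcm_features(droi_from_levels(lv1))
  expect_equal(unname(f1["MaximumProbability"]), 1)
  expect_equal(unname(f1["MCC"]), 1)
})

test_that("per-direction GLCM matrices are symmetric and normalized", {
  set.seed(34)
  for (rep in 1:10) {
    lv <- random_levels(c(5, 6, 4), ng = 4, fill = 0.7)
    counts <- radagree:::cpp_glcm(lv, max(lv))
    for (d in 1:13) {
      C <- matrix(counts[, , d], max(lv), max(lv))
      expect_equal(C, t(C))
      if (sum(C) > 0) expect_equal(sum(C / sum(C)), 1)
    }
  }
})

test_that("run/zone/dependence matrices on a hand-checked 1x1x5 ROI", {
  lv <- array(c(1L, 1L, 1L, 2L, 2L), c(1, 1, 5))
  droi <- droi_from_levels(lv)
  expect_equal(glrlm_features(droi), oracle_glrlm_features(lv, 2),
               tolerance = 1e-12)
  expect_equal(glszm_features(droi), oracle_glszm_features(lv, 2),
               tolerance = 1e-12)
  expect_equal(gldm_features(droi), oracle_gldm_features(lv, 2),
               tolerance = 1e-12)
  expect_equal(ngtdm_features(droi), oracle_ngtdm_features(lv, 2),
               tolerance = 1e-12)
  # run matrix along z: runs (1,len3) and (2,len2); 13 directions averaged,
  # 12 of them see runs of length 1 only
  f <- glrlm_features(droi)
  expect_equal(unname(f["RunPercentage"]), (2 + 12 * 5) / (13 * 5))
})

test_that("constant 3x3x3 ROI collapses zones and NGTDM as defined", {
  lv <- array(1L, c(3, 3, 3))
  droi <- droi_from_levels(lv)
  z <- radagree:::cpp_glszm_zones(lv)
  expect_equal(nrow(z), 1L)
  expect_equal(z[1, 2], 27L)
  expect_equal(unname(glszm_features(droi)["GrayLevelVariance"]), 0)
  expect_equal(unname(ngtdm_features(droi)["Complexity"]), 0)
})

test_that("GLSZM zone sizes partition the ROI voxel count", {
  set.seed(35)
  for (rep in 1:10) {
    lv <- random_levels(c(5, 5, 5), ng = 3, fill = 0.6)
    z <- radagree:::cpp_glszm_zones(lv)
    expect_equal(sum(z[, 2]), sum(lv > 0))
  }
})

test_that("shifting all intensities leaves texture untouched and moves first-order", {
  set.seed(36)
  vox <- array(rnorm(6^3, 0, 30), c(6, 6, 6))
  img1 <- image_volume(vox)
  img2 <- image_volume(vox + 1000)
  msk <- random_mask(c(6, 6, 6), p = 0.8)
  d1 <- discretize(img1, msk, 25); d2 <- discretize(img2, msk, 25)
  expect_identical(d1$levels, d2$levels)
  expect_equal(glcm_features(d1), glcm_features(d2))
  f1 <- first_order_features(img1, msk, d1)
  f2 <- first_order_features(img2, msk, d2)
  expect_equal(unname(f2["Maximum"] - f1["Maximum"]), 1000)
  expect_equal(unname(f2["Median"] - f1["Median"]), 1000)
})
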