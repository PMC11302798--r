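# a desk-scale spec keeps the per-test cost low; geometry-only checks do not
# need the full 64^3 default
small_spec <- function(seed = 1, ...) {
  phantom_spec(n_tumors = 2, grid = 48, radius_range_mm = c(14, 17),
               seed = seed, ...)
}

test_that("tumor generation is bit-identical under the same seed and index", {
  s <- small_spec(seed = 9)
  a <- make_tumor(s, 1)
  b <- make_tumor(s, 1)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  c2 <- make_tumor(s, 2)
  expect_false(identical(a$image$voxels, c2$image$voxels))
  expect_gte(sum(a$mask$voxels), 1)
})

test_that("zero noise and texture give a constant-valued tumor ROI", {
  s <- small_spec(noise_amplitude = 0, texture_amplitude = 0, heterogeneity = 0)
  tm <- make_tumor(s, 1)
  vals <- tm$image$voxels[tm$mask$voxels == 1L]
  expect_lt(diff(range(vals)), 1e-12)
  expect_equal(unique(vals), s$contrast)
})

test_that("ROI-background contrast tracks the configured value", {
  # Monte-Carlo check of the generator's stated intensity model
  diffs <- vapply(1:12, function(s) {
    tm <- make_tumor(small_spec(seed = s), 1)
    roi <- tm$image$voxels[tm$mask$voxels == 1L]
    bg <- tm$image$voxels[tm$mask$voxels == 0L]
    mean(roi) - mean(bg)
  }, numeric(1))
  # per-tumor contrast is uniform in 100 +/- 40%; the mean should sit near
  # 100 within ~3 standard errors
  expect_lt(abs(mean(diffs) - 100), 3 * sd(diffs) / sqrt(length(diffs)) + 5)
})

test_that("zero-level perturbations are the identity", {
  tm <- make_tumor(small_spec(), 1)
  for (kind in c("boundary_jitter", "systematic_dilation",
                 "systematic_erosion_offset")) {
    fam <- perturbation_family(kind, c(0, 1))
    expect_identical(perturb(tm$mask, fam, 1, seed = 5)$voxels, tm$mask$voxels)
  }
})

test_that("dilation then erosion of a convex mask contains the original", {
  tm <- make_tumor(small_spec(seed = 3), 1)
  dil <- perturb(tm$mask, perturbation_family("systematic_dilation", 2), 1)
  # closing: erode the dilated mask by the same radius
  ero <- radagree:::.apply_perturbation(dil, "systematic_erosion_offset", 2,
                                        c(0, 0, 0), seed = 1)
  expect_true(all(ero$voxels[tm$mask$voxels == 1L] == 1L))
})

test_that("dilation volume growth matches the analytic shell within tolerance", {
  # 10 mm ball at 2 mm spacing dilated by 2 mm
  n <- 24
  x <- ((1:n) - (n + 1) / 2) * 2
  r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  ball <- label_mask(array(as.integer(r2 <= 10^2), c(n, n, n)),
                     spacing = c(2, 2, 2))
  dil <- perturb(ball, perturbation_family("systematic_dilation", 2), 1)
  v0 <- sum(ball$voxels) * 8
  v1 <- sum(dil$voxels) * 8
  shell <- 4 / 3 * pi * (12^3 - 10^3)
  # voxelization at 2 mm is coarse; require agreement within 25%
  expect_lt(abs((v1 - v0) - shell) / shell, 0.25)
})

test_that("erosion+offset shifts and shrinks without emptying", {
  tm <- make_tumor(small_spec(seed = 4), 1)
  fam <- perturbation_family("systematic_erosion_offset", c(2), offset_mm = c(1, 0, 0))
  out <- perturb(tm$mask, fam, 1)
  expect_lt(sum(out$voxels), sum(tm$mask$voxels))
  expect_gte(sum(out$voxels), 1)
})

test_that("perturbing an over-aggressive level falls back instead of emptying", {
  v <- array(0L, c(12, 12, 12)); v[6:7, 6:7, 6:7] <- 1L
  tiny <- label_mask(v)
  fam <- perturbation_family("systematic_erosion_offset", 6)
  w <- capture_warnings(out <- perturb(tiny, fam, 1))
  expect_true(length(w) >= 1 && all(grepl("emptied", w)))
  expect_gte(sum(out$voxels), 1)
})

test_that("cohorts have the configured layout and respect the DSC floor", {
  s <- phantom_spec(n_tumors = 2, seed = 11)
  co <- make_cohort(s)
  expect_equal(length(co$tumors), 2L)
  expect_equal(length(co$segmentation_ids), 9L)
  expect_equal(nrow(pairwise_metrics(co$tumors[[1]]$masks)), 36L)
  for (tm in co$tumors) {
    pm <- pairwise_metrics(tm$masks)
    expect_gt(min(pm$dsc), s$dsc_floor)
  }
  # determinism of the full cohort
  co2 <- make_cohort(s)
  expect_identical(co$tumors[[1]]$masks[[5]]$voxels, co2$tumors[[1]]$masks[[5]]$voxels)
})

test_that("a single family with zero levels gives all pairwise DSC of 1", {
  s <- phantom_spec(n_tumors = 1,
                    families = list(same = perturbation_family("boundary_jitter",
                                                               c(0, 0))),
                    grid = 48, radius_range_mm = c(12, 14), seed = 2)
  co <- make_cohort(s)
  pm <- pairwise_metrics(co$tumors[[1]]$masks)
  expect_true(all(pm$dsc == 1))
})

test_that("planted family labels follow the family x setting layout", {
  truth <- planted_families(phantom_spec())
  expect_equal(length(truth), 9L)
  expect_equal(as.integer(table(truth)), c(3L, 3L, 3L))
  expect_equal(truth[["jitter_2"]], 1L)
  expect_equal(truth[["erode_3"]], 3L)
})
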