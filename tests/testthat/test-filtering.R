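# symmetric (edge-repeating mirror) index, the boundary rule shared by all
# filters; reimplemented here for the brute-force convolution oracle
reflect_idx <- function(i, n) {
  if (n == 1) return(1)
  j <- (i - 1) %% (2 * n)
  if (j < 0) j <- j + 2 * n
  if (j < n) j + 1 else 2 * n - j
}

naive_convolve_axis <- function(arr, kernel, axis, center) {
  dims <- dim(arr)
  out <- array(0, dims)
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    pos <- c(i, j, k)
    acc <- 0
    for (t in seq_along(kernel)) {
      p <- pos
      p[axis] <- reflect_idx(pos[axis] + (t - 1) - center, dims[axis])
      acc <- acc + kernel[t] * arr[p[1], p[2], p[3]]
    }
    out[i, j, k] <- acc
  }
  out
}

test_that("resampling follows extent/spacing arithmetic and preserves constants", {
  img <- image_volume(array(7.5, c(8, 8, 8)), spacing = c(1, 1, 1))
  v <- array(0L, c(8, 8, 8)); v[3:6, 3:6, 3:6] <- 1L
  msk <- label_mask(v)
  out <- resample(img, msk, filter_config(resample_spacing_mm = 2))
  expect_equal(dim(out$image$voxels), c(4L, 4L, 4L))
  expect_equal(dim(out$mask$voxels), c(4L, 4L, 4L))
  expect_true(all(abs(out$image$voxels - 7.5) < 1e-12))
  expect_true(sum(out$mask$voxels) >= 1)
  expect_equal(out$image$spacing, c(2, 2, 2))
  # grids are center-aligned over the same physical extent
  expect_equal(out$image$origin, img$origin + (7 - 3 * 2) / 2)
})

test_that("resampling a single-voxel mask to coarser spacing can degenerate", {
  img <- image_volume(array(0, c(9, 9, 9)))
  v <- array(0L, c(9, 9, 9)); v[1, 1, 1] <- 1L  # far off the coarse lattice
  expect_error(resample(img, label_mask(v), filter_config(resample_spacing_mm = 4)),
               "degenerate-ROI")
})

test_that("LoG of a constant is zero and of a ramp is zero in the interior", {
  const <- image_volume(array(3, c(10, 10, 10)))
  expect_true(max(abs(log_filter(const, 1)$voxels)) < 1e-12)
  ramp <- image_volume(array(rep(1:12, times = 12 * 12), c(12, 12, 12)))
  resp <- log_filter(ramp, 1)$voxels
  expect_true(max(abs(resp[5:8, 5:8, 5:8])) < 1e-9)
})

test_that("LoG impulse response matches the closed-form kernel", {
  n <- 17
  arr <- array(0, c(n, n, n)); arr[9, 9, 9] <- 1
  sigma <- 2
  resp <- log_filter(image_volume(arr), sigma)$voxels
  x <- (1:n) - 9
  g <- function(x) exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  g2 <- function(x) (x^2 - sigma^2) / sigma^4 * g(x)
  closed <- array(0, c(n, n, n))
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    closed[i, j, k] <- g2(x[i]) * g(x[j]) * g(x[k]) +
      g(x[i]) * g2(x[j]) * g(x[k]) + g(x[i]) * g(x[j]) * g2(x[k])
  }
  expect_lt(max(abs(resp - closed)), 0.02 * max(abs(closed)))
})

test_that("LoG warns when sigma is under-resolved", {
  img <- image_volume(array(rnorm(5^3), c(5, 5, 5)), spacing = c(2, 2, 2))
  expect_warning(log_filter(img, 0.5), "under-resolved")
})

test_that("wavelet sub-bands: constants vanish under H and persist under LLL", {
  const <- image_volume(array(5, c(8, 8, 8)))
  sub <- wavelet_decompose(const, "coif1")
  expect_equal(names(sub),
               c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH"))
  for (lab in names(sub)) {
    if (grepl("H", lab)) {
      expect_lt(max(abs(sub[[lab]]$voxels)), 1e-10)
    } else {
      expect_lt(diff(range(sub[[lab]]$voxels)), 1e-10)
    }
  }
})

test_that("wavelet sub-bands match brute-force separable convolution", {
  set.seed(21)
  arr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  img <- image_volume(arr)
  fl <- radagree:::.wavelet_filters$coif1
  ctr <- (length(fl$lo) - 1) %/% 2  # same 0-based center as the implementation
  sub <- wavelet_decompose(img, "coif1")
  for (lab in c("LLL", "HLL", "LHH", "HHH")) {
    ref <- arr
    for (ax in 1:3) {
      kern <- if (substr(lab, ax, ax) == "L") fl$lo else fl$hi
      ref <- naive_convolve_axis(ref, kern, ax, ctr)
    }
    expect_equal(sub[[lab]]$voxels, ref, tolerance = 1e-12)
  }
})

test_that("filters are linear", {
  set.seed(22)
  x <- image_volume(array(rnorm(6^3), c(6, 6, 6)))
  y <- image_volume(array(rnorm(6^3), c(6, 6, 6)))
  lin <- image_volume(2 * x$voxels - 3 * y$voxels)
  expect_equal(log_filter(lin, 1)$voxels,
               2 * log_filter(x, 1)$voxels - 3 * log_filter(y, 1)$voxels,
               tolerance = 1e-10)
  wx <- wavelet_decompose(x); wy <- wavelet_decompose(y); wl <- wavelet_decompose(lin)
  expect_equal(wl$HLH$voxels, 2 * wx$HLH$voxels - 3 * wy$HLH$voxels,
               tolerance = 1e-10)
})

test_that("derived image-type count is 10 under defaults", {
  cfg <- filter_config()
  expect_equal(length(image_types(cfg)), 10L)
  img <- image_volume(array(rnorm(6^3), c(6, 6, 6)))
  der <- derive_images(img, cfg)
  expect_equal(names(der), image_types(cfg))
  expect_error(filter_config(wavelet = "nosuch"), "config error")
})
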