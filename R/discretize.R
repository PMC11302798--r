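#' Fixed-bin-width gray-level discretization of an ROI
#'
#' Maps ROI intensities to integer gray levels with
#' `level = floor((x - bin_origin) / bin_width) + 1`. Under the default rule
#' the bin origin is the ROI minimum, so level 1 is always occupied;
#' `origin_rule = "aligned"` instead anchors bin edges at integer multiples
#' of the bin width (origin = `bin_width * floor(min / bin_width)`).
#'
#' @param image An [image_volume()].
#' @param mask A nonempty [label_mask()] aligned with `image`.
#' @param bin_width Positive bin width in intensity units (default 25).
#' @param origin_rule `"roi-min"` (default) or `"aligned"`.
#' @return A `discretized_roi`: list with `levels` (integer array, 0 outside
#'   the ROI), `ng` (number of levels up to the occupied maximum), `bin_width`
#'   and `bin_origin`.
#' @export
discretize <- function(image, mask, bin_width = 25, origin_rule = c("roi-min", "aligned")) {
  origin_rule <- match.arg(origin_rule)
  assert_aligned(image, mask)
  if (bin_width <= 0) stop("bin_width must be positive")
  idx <- mask$voxels == 1L
  if (!any(idx)) stop("degenerate-ROI error: empty mask")
  x <- image$voxels[idx]
  bin_origin <- if (origin_rule == "roi-min") min(x) else bin_width * floor(min(x) / bin_width)
  lev <- as.integer(floor((x - bin_origin) / bin_width)) + 1L
  levels <- array(0L, dim(mask$voxels))
  levels[idx] <- lev
  structure(list(levels = levels, ng = max(lev), bin_width = bin_width,
                 bin_origin = bin_origin, n_voxels = length(x)),
            class = "discretized_roi")
}

#' First-order (intensity statistic) features
#'
#' The 18 standard first-order features. Order statistics (Maximum, Median,
#' percentiles, ...) are computed on the raw (possibly filtered) ROI
#' intensities; Entropy and Uniformity use the discretized histogram.
#' Energy is the sum of squared intensities; TotalEnergy scales it by the
#' voxel volume in mm^3. Skewness and Kurtosis use population moments
#' (Kurtosis is not excess-corrected); both are 0 for a constant ROI.
#'
#' @param image An [image_volume()] (original or filtered intensities).
#' @param mask A nonempty [label_mask()].
#' @param droi The [discretize()]d ROI of the same image/mask.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(image, mask, droi) {
  x <- image$voxels[mask$voxels == 1L]
  if (length(x) < 1) stop("degenerate-ROI error: empty mask")
  n <- length(x)
  vox_mm3 <- prod(image$spacing)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  p10 <- qs[1]; p25 <- qs[2]; p75 <- qs[3]; p90 <- qs[4]
  sub <- x[x >= p10 & x <= p90]
  counts <- tabulate(droi$levels[droi$levels > 0], nbins = droi$ng)
  p <- counts / sum(counts)
  pn <- p[p > 0]
  eps <- 2.220446e-16
  c(
    Energy = sum(x^2),
    TotalEnergy = vox_mm3 * sum(x^2),
    Entropy = -sum(pn * log2(pn + eps)),
    Minimum = min(x),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = p75 - p25,
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(sub - mean(sub))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pn^2)
  )
}
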