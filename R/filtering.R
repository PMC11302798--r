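# Preprocessing filter bank: isotropic resampling, Laplacian-of-Gaussian,
# and a single-level stationary (undecimated) separable 3-D wavelet
# decomposition. One boundary rule is used everywhere: symmetric (mirror,
# edge-repeating) padding.

# Orthonormal decomposition filter pairs (low, high). Taps are the standard
# published coefficients for each family.
.wavelet_filters <- list(
  coif1 = list(
    lo = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
            0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    hi = c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
           0.3848648468648578, 0.07273261951252645, -0.015655728135791993)),
  haar = list(
    lo = c(0.7071067811865476, 0.7071067811865476),
    hi = c(-0.7071067811865476, 0.7071067811865476)),
  db2 = list(
    lo = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
            0.48296291314453416),
    hi = c(-0.48296291314453416, 0.8365163037378079, -0.2241438680420134,
           -0.12940952255126037))
)

#' Filter-bank configuration
#'
#' Bundles every preprocessing knob: target resampling spacing, LoG sigmas,
#' wavelet family and interpolators. The derived image-type set under the
#' defaults is 1 original + 1 LoG + 8 wavelet sub-bands = 10 types.
#'
#' @param resample_spacing_mm Target voxel size in mm (length 3 or scalar).
#' @param log_sigmas_mm Gaussian widths (mm) for the Laplacian-of-Gaussian
#'   filter; one derived image per sigma.
#' @param wavelet Wavelet family for the stationary decomposition; one of
#'   `"coif1"`, `"haar"`, `"db2"`.
#' @param image_interpolator Interpolator for scalar volumes (`"trilinear"`).
#' @param mask_interpolator Interpolator for masks (`"nearest"` only).
#' @return A `filter_config` list.
#' @export
filter_config <- function(resample_spacing_mm = c(2, 2, 2),
                          log_sigmas_mm = 1.0,
                          wavelet = "coif1",
                          image_interpolator = "trilinear",
                          mask_interpolator = "nearest") {
  if (length(resample_spacing_mm) == 1) resample_spacing_mm <- rep(resample_spacing_mm, 3)
  if (length(resample_spacing_mm) != 3 || any(resample_spacing_mm <= 0))
    stop("resample_spacing_mm must be 3 positive values")
  if (any(log_sigmas_mm <= 0)) stop("log_sigmas_mm must be positive")
  if (!wavelet %in% names(.wavelet_filters))
    stop("config error: unknown wavelet '", wavelet, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "))
  image_interpolator <- match.arg(image_interpolator, "trilinear")
  mask_interpolator <- match.arg(mask_interpolator, "nearest")
  structure(list(resample_spacing_mm = as.numeric(resample_spacing_mm),
                 log_sigmas_mm = as.numeric(log_sigmas_mm),
                 wavelet = wavelet,
                 image_interpolator = image_interpolator,
                 mask_interpolator = mask_interpolator),
            class = "filter_config")
}

#' Image types produced by a configuration
#' @param config A [filter_config()].
#' @return Character vector of image-type labels, original first.
#' @export
image_types <- function(config = filter_config()) {
  logs <- sprintf("log-sigma-%s-mm-3D",
                  gsub("\\.", "-", sprintf("%.1f", config$log_sigmas_mm)))
  wl <- paste0("wavelet-",
               apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")),
                     1, paste, collapse = ""))
  c("original", logs, wl)
}

.resample_grid <- function(dims, spacing, origin, new_spacing) {
  # cover the physical extent (dims * spacing) at the new spacing, grids
  # center-aligned so both samplings see the same physical region
  newdim <- pmax(1L, as.integer(round(dims * spacing / new_spacing)))
  neworigin <- origin + ((dims - 1) * spacing - (newdim - 1) * new_spacing) / 2
  list(dim = newdim, origin = neworigin)
}

#' Resample an image and its mask to a target spacing
#'
#' The output grid covers the input's physical extent at the target spacing,
#' center-aligned with the input grid. The image is interpolated trilinearly,
#' the mask with nearest-neighbor and re-binarized.
#'
#' @param image An [image_volume()].
#' @param mask A [label_mask()] aligned with `image`.
#' @param config A [filter_config()]; only the resampling fields are used.
#' @return `list(image = , mask = )` on the new common grid.
#' @export
resample <- function(image, mask, config = filter_config()) {
  assert_aligned(image, mask)
  sp <- config$resample_spacing_mm
  g <- .resample_grid(dim(image$voxels), image$spacing, image$origin, sp)
  vox <- cpp_resample_trilinear(image$voxels, image$spacing, image$origin,
                                g$dim, sp, g$origin)
  mvox <- cpp_resample_nearest(array(as.double(mask$voxels), dim(mask$voxels)),
                               mask$spacing, mask$origin, g$dim, sp, g$origin)
  mvox <- array(as.integer(mvox >= 0.5), g$dim)
  if (sum(mvox) < 1)
    stop("degenerate-ROI error: mask became empty after resampling to ",
         paste(sp, collapse = "x"), " mm")
  list(image = image_volume(vox, sp, g$origin),
       mask = label_mask(mvox, sp, g$origin))
}

.gaussian_kernel <- function(sigma_mm, spacing_mm, radius_sd = 4) {
  r <- max(1L, as.integer(ceiling(radius_sd * sigma_mm / spacing_mm)))
  x <- (-r:r) * spacing_mm
  k <- exp(-x^2 / (2 * sigma_mm^2))
  k / sum(k)
}

.gaussian_d2_kernel <- function(sigma_mm, spacing_mm, radius_sd = 4) {
  # sampled second derivative of a Gaussian, zero-sum corrected so a constant
  # image maps exactly to zero
  r <- max(1L, as.integer(ceiling(radius_sd * sigma_mm / spacing_mm)))
  x <- (-r:r) * spacing_mm
  g <- exp(-x^2 / (2 * sigma_mm^2)) / (sigma_mm * sqrt(2 * pi))
  k <- (x^2 - sigma_mm^2) / sigma_mm^4 * g * spacing_mm
  k - mean(k)
}

#' Laplacian-of-Gaussian filter
#'
#' Applies the 3-D LoG with isotropic physical width `sigma_mm`, implemented
#' as the sum over axes of a separable second-derivative-of-Gaussian kernel
#' (plain Gaussian smoothing along the two remaining axes). Kernels are
#' sampled on each axis' own spacing, so anisotropic grids are handled
#' correctly. Symmetric boundary padding.
#'
#' @param image An [image_volume()].
#' @param sigma_mm Positive Gaussian width in mm.
#' @return An [image_volume()] on the same grid.
#' @export
log_filter <- function(image, sigma_mm = 1.0) {
  if (sigma_mm <= 0) stop("sigma_mm must be positive")
  if (sigma_mm < min(image$spacing) / 2)
    warning("LoG sigma ", sigma_mm, " mm is under-resolved at spacing ",
            paste(image$spacing, collapse = "/"), " mm")
  out <- array(0, dim(image$voxels))
  smooth <- lapply(1:3, function(a) .gaussian_kernel(sigma_mm, image$spacing[a]))
  deriv <- lapply(1:3, function(a) .gaussian_d2_kernel(sigma_mm, image$spacing[a]))
  for (a in 1:3) {
    part <- image$voxels
    for (b in 1:3) {
      k <- if (b == a) deriv[[b]] else smooth[[b]]
      part <- cpp_convolve_axis(part, k, b, (length(k) - 1L) %/% 2L)
    }
    out <- out + part
  }
  image_volume(out, image$spacing, image$origin)
}

#' Single-level stationary 3-D wavelet decomposition
#'
#' Undecimated separable transform: the low- (`L`) or high-pass (`H`)
#' decomposition filter is applied along each grid axis, giving 8 sub-bands
#' on the input grid. The i-th letter of a sub-band label names the filter
#' applied along grid axis i (first letter = first/fastest axis). Symmetric
#' boundary padding; no decimation, so every sub-band shares the ROI grid.
#'
#' @param image An [image_volume()].
#' @param wavelet Wavelet family name (see [filter_config()]).
#' @return Named list of 8 [image_volume()]s: `LLL`, `HLL`, `LHL`, ...,
#'   `HHH`.
#' @export
wavelet_decompose <- function(image, wavelet = "coif1") {
  fl <- .wavelet_filters[[wavelet]]
  if (is.null(fl)) stop("config error: unknown wavelet '", wavelet, "'")
  ctr <- (length(fl$lo) - 1L) %/% 2L
  bands <- expand.grid(a1 = c("L", "H"), a2 = c("L", "H"), a3 = c("L", "H"),
                       stringsAsFactors = FALSE)
  out <- list()
  for (r in seq_len(nrow(bands))) {
    lab <- paste0(bands$a1[r], bands$a2[r], bands$a3[r])
    vox <- image$voxels
    for (ax in 1:3) {
      k <- if (bands[r, ax] == "L") fl$lo else fl$hi
      vox <- cpp_convolve_axis(vox, k, ax, ctr)
    }
    out[[lab]] <- image_volume(vox, image$spacing, image$origin)
  }
  out[c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")]
}

#' Derive the full image-type set used by the feature panel
#'
#' @param image A (typically already resampled) [image_volume()].
#' @param config A [filter_config()].
#' @param types Optional character vector restricting which image types to
#'   compute (labels as in [image_types()]).
#' @return Named list image-type label -> [image_volume()].
#' @export
derive_images <- function(image, config = filter_config(), types = NULL) {
  all_types <- image_types(config)
  if (is.null(types)) types <- all_types
  unknown <- setdiff(types, all_types)
  if (length(unknown) > 0)
    stop("unknown image type(s): ", paste(unknown, collapse = ", "))
  out <- list()
  if ("original" %in% types) out[["original"]] <- image
  for (i in seq_along(config$log_sigmas_mm)) {
    lab <- all_types[1 + i]
    if (lab %in% types) out[[lab]] <- log_filter(image, config$log_sigmas_mm[i])
  }
  wl_types <- grep("^wavelet-", types, value = TRUE)
  if (length(wl_types) > 0) {
    sub <- wavelet_decompose(image, config$wavelet)
    for (lab in wl_types) out[[lab]] <- sub[[sub("wavelet-", "", lab)]]
  }
  out[intersect(types, names(out))]
}
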