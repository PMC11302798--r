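# Seeded synthetic cohort generator: N ellipsoidal tumors with correlated
# internal texture, each segmented k times by g perturbation families whose
# settings differ only in level. One family perturbs the boundary randomly;
# the two others are systematic (dilation; erosion plus a rigid offset), so
# the cohort exercises exactly the systematic-versus-random error contrast
# that absolute-agreement ICC is sensitive to and plain overlap metrics are
# not. Everything is reproducible from the single top-level seed through
# hierarchical sub-seeding per tumor and per family.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.sub_seed <- function(seed, ...) {
  # deterministic sub-stream id, kept inside the 32-bit integer range
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) acc <- (acc * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(acc)
}

#' Perturbation family description
#'
#' @param kind `"boundary_jitter"` (random smooth surface displacement with
#'   the given sigma in mm), `"systematic_dilation"` (morphological dilation
#'   by the level radius in mm) or `"systematic_erosion_offset"` (erosion by
#'   the level radius plus a rigid shift of `offset_mm * level`).
#' @param levels Numeric vector of per-setting levels in mm; one segmentation
#'   per level.
#' @param offset_mm Direction/magnitude basis of the rigid shift (only used
#'   by `"systematic_erosion_offset"`).
#' @return A `perturbation_family` list.
#' @export
perturbation_family <- function(kind = c("boundary_jitter", "systematic_dilation",
                                         "systematic_erosion_offset"),
                                levels, offset_mm = c(1, 0, 0)) {
  kind <- match.arg(kind)
  if (any(levels < 0)) stop("levels must be nonnegative (mm)")
  structure(list(kind = kind, levels = as.numeric(levels),
                 offset_mm = as.numeric(offset_mm)),
            class = "perturbation_family")
}

#' Phantom cohort specification
#'
#' Defaults emulate the study design the toolkit targets: 10 tumors, each
#' with 9 segmentations from 3 method families x 3 settings, tumor semi-axes
#' 20-26 mm on a 64^3 grid at 1 mm spacing, with within-family boundary
#' perturbations small and cross-family ones systematic, tuned so every
#' within-tumor pairwise DSC stays above the `dsc_floor`.
#'
#' @param n_tumors Number of tumors (default 10).
#' @param families List of [perturbation_family()] objects (default 3
#'   families x 3 levels = 9 segmentations). Default levels are of the order
#'   of one voxel: large enough to act on the 1 mm grid, small enough that
#'   every pair of segmentations still overlaps heavily.
#' @param grid Grid size per axis in voxels (default 64).
#' @param spacing_mm Voxel spacing in mm (default 1).
#' @param radius_range_mm Range of ellipsoid semi-axes in mm.
#' @param contrast Mean tumor-minus-background intensity difference.
#' @param texture_amplitude SD of the correlated texture inside the tumor.
#' @param texture_length_mm Correlation length (Gaussian sigma) of the
#'   texture field in mm.
#' @param noise_amplitude SD of the additive white noise.
#' @param heterogeneity Relative tumor-to-tumor variation of contrast and
#'   texture amplitude (each tumor scales them by a factor drawn uniformly
#'   from `1 +/- heterogeneity`), emulating the strong between-patient
#'   variability of real tumors that makes most radiomics features
#'   reproducible across segmentations.
#' @param dsc_floor Lowest admissible within-tumor pairwise DSC; levels are
#'   scaled down (bounded retries) if generation violates it.
#' @param seed Top-level seed; every volume and mask is a deterministic
#'   function of it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_tumors = 10,
                         families = list(
                           jitter = perturbation_family("boundary_jitter",
                                                        c(1.0, 1.1, 1.2)),
                           dilate = perturbation_family("systematic_dilation",
                                                        c(1.45, 1.6, 1.75)),
                           erode = perturbation_family("systematic_erosion_offset",
                                                       c(1.0, 1.15, 1.3),
                                                       offset_mm = c(0.8, 0.6, 0))),
                         grid = 64, spacing_mm = 1,
                         radius_range_mm = c(20, 26),
                         contrast = 100, texture_amplitude = 30,
                         texture_length_mm = 3, noise_amplitude = 10,
                         heterogeneity = 0.4,
                         dsc_floor = 0.75, seed = 1) {
  k <- sum(vapply(families, function(f) length(f$levels), integer(1)))
  if (k < 2) stop("families x settings must give at least 2 segmentations")
  stopifnot(grid >= 8, spacing_mm > 0, all(radius_range_mm > 0),
            texture_length_mm > 0, dsc_floor >= 0, dsc_floor < 1)
  if (max(radius_range_mm) * 2 + 8 > grid * spacing_mm)
    stop("spec error: tumors would not fit the grid")
  structure(list(n_tumors = n_tumors, families = families, grid = grid,
                 spacing_mm = spacing_mm, radius_range_mm = radius_range_mm,
                 contrast = contrast, texture_amplitude = texture_amplitude,
                 texture_length_mm = texture_length_mm,
                 noise_amplitude = noise_amplitude,
                 heterogeneity = heterogeneity,
                 dsc_floor = dsc_floor, seed = as.integer(seed)),
            class = "phantom_spec")
}

.smooth_field <- function(dims, sigma_mm, spacing_mm) {
  # Gaussian-filtered white noise, rescaled to unit variance
  f <- array(rnorm(prod(dims)), dims)
  k <- .gaussian_kernel(sigma_mm, spacing_mm)
  for (ax in 1:3) f <- cpp_convolve_axis(f, k, ax, (length(k) - 1L) %/% 2L)
  (f - mean(f)) / max(sd(f), 1e-12)
}

#' Generate one phantom tumor
#'
#' An ellipsoidal tumor (semi-axes drawn from `radius_range_mm`, center
#' jittered around the grid center) with smoothly varying internal texture
#' on a darker background plus white noise; the true mask is the ellipsoid's
#' voxelization. Fully determined by `(spec$seed, tumor_index)`.
#'
#' @param spec A [phantom_spec()].
#' @param tumor_index 1-based tumor index.
#' @return `list(image = image_volume, mask = label_mask)`.
#' @export
make_tumor <- function(spec, tumor_index) {
  n <- spec$grid
  sp <- rep(spec$spacing_mm, 3)
  dims <- rep(n, 3)
  .with_seed(.sub_seed(spec$seed, 101, tumor_index), {
    semi <- runif(3, spec$radius_range_mm[1], spec$radius_range_mm[2])
    center <- (dims - 1) / 2 * sp + runif(3, -1, 1)
    h <- spec$heterogeneity
    contrast_t <- spec$contrast * runif(1, 1 - h, 1 + h)
    amp_t <- spec$texture_amplitude * runif(1, 1 - h, 1 + h)
    ax <- lapply(1:3, function(a) ((seq_len(n) - 1) * sp[a] - center[a]))
    ell <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, `+`),
                 (ax[[3]] / semi[3])^2, `+`)
    mask_arr <- array(as.integer(ell <= 1), dims)
    texture <- .smooth_field(dims, spec$texture_length_mm, spec$spacing_mm)
    noise <- array(rnorm(prod(dims), 0, spec$noise_amplitude), dims)
    vox <- contrast_t * (ell <= 1) + amp_t * texture * (ell <= 1) + noise
    list(image = image_volume(vox, sp, c(0, 0, 0)),
         mask = label_mask(mask_arr, sp, c(0, 0, 0)))
  })
}

.mask_distances <- function(mask) {
  # distance to foreground (0 on it) and to background, both in mm
  inv <- mask$voxels
  inv[] <- as.integer(mask$voxels == 0L)
  list(d_fg = cpp_edt(mask$voxels, mask$spacing),
       d_bg = cpp_edt(inv, mask$spacing))
}

.apply_perturbation <- function(mask, kind, level, offset_mm, seed,
                                dists = NULL) {
  if (level == 0) return(mask)
  if (is.null(dists)) dists <- .mask_distances(mask)
  vox <- switch(kind,
    boundary_jitter = {
      sdist <- dists$d_fg - dists$d_bg   # negative inside
      f <- .with_seed(seed, .smooth_field(dim(mask$voxels), 3, mask$spacing[1]))
      array(as.integer(sdist + level * f < 0), dim(mask$voxels))
    },
    systematic_dilation = {
      array(as.integer(dists$d_fg <= level + 1e-9), dim(mask$voxels))
    },
    systematic_erosion_offset = {
      er <- array(as.integer(mask$voxels == 1L & dists$d_bg > level + 1e-9),
                  dim(mask$voxels))
      shift_vox <- round(offset_mm * level / mask$spacing)
      out <- array(0L, dim(er))
      d3 <- dim(er)
      src <- lapply(1:3, function(a) {
        idx <- seq_len(d3[a]) - shift_vox[a]
        idx[idx < 1 | idx > d3[a]] <- NA
        idx
      })
      ok <- lapply(src, function(v) !is.na(v))
      out[ok[[1]], ok[[2]], ok[[3]]] <-
        er[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
      out
    },
    stop("unknown perturbation kind: ", kind))
  label_mask(vox, mask$spacing, mask$origin)
}

#' Perturb a mask with one family setting
#'
#' Zero-level perturbations return the mask unchanged. If a perturbation
#' empties the mask, the level is halved and retried (at most 5 times)
#' with a warning; persistent failure is an error.
#'
#' @param mask A nonempty [label_mask()].
#' @param family A [perturbation_family()].
#' @param setting 1-based index into `family$levels`.
#' @param seed Seed for the random jitter field (ignored by the systematic
#'   kinds).
#' @return A nonempty [label_mask()].
#' @export
perturb <- function(mask, family, setting, seed = 1) {
  if (n_foreground(mask) < 1) stop("cannot perturb an empty mask")
  level <- family$levels[setting]
  dists <- .mask_distances(mask)
  for (attempt in 1:5) {
    out <- .apply_perturbation(mask, family$kind, level, family$offset_mm,
                               seed, dists)
    if (n_foreground(out) >= 1) return(out)
    warning("perturbation emptied the mask; retrying at level ", level / 2)
    level <- level / 2
  }
  stop("perturbation emptied the mask after 5 attempts")
}

#' Generate a full phantom cohort
#'
#' `n_tumors` tumors, each with one segmentation per family setting, labeled
#' `<family>_<setting>`. After generation every within-tumor pairwise DSC is
#' checked against `spec$dsc_floor`; a violating tumor is regenerated with
#' all family levels scaled down by 20% (up to 5 rounds) before failing.
#'
#' @param spec A [phantom_spec()].
#' @return A [cohort()] (default spec: 10 tumors x 9 segmentations).
#' @export
make_cohort <- function(spec = phantom_spec()) {
  tumors <- list()
  for (t in seq_len(spec$n_tumors)) {
    base <- make_tumor(spec, t)
    dists <- .mask_distances(base$mask)
    fams <- spec$families
    done <- FALSE
    for (round in 1:5) {
      masks <- list()
      for (fi in seq_along(fams)) {
        fam <- fams[[fi]]
        fname <- names(fams)[fi]
        if (is.null(fname) || fname == "") fname <- paste0("f", fi)
        for (si in seq_along(fam$levels)) {
          sid <- paste0(fname, "_", si)
          # one random field per (tumor, family): a family's settings share
          # the same characteristic error pattern at different strengths,
          # like one piece of software run with different parameters
          masks[[sid]] <- .apply_perturbation(
            base$mask, fam$kind, fam$levels[si], fam$offset_mm,
            seed = .sub_seed(spec$seed, 202, t, fi), dists = dists)
          if (n_foreground(masks[[sid]]) < 1)
            stop("spec error: perturbation ", sid, " emptied tumor ", t)
        }
      }
      counts <- vapply(masks, n_foreground, numeric(1))
      dmin <- 1
      ids <- names(masks)
      for (i in seq_len(length(ids) - 1))
        for (j in (i + 1):length(ids)) {
          inter <- sum(masks[[i]]$voxels & masks[[j]]$voxels)
          dmin <- min(dmin, 2 * inter / (counts[i] + counts[j]))
        }
      if (dmin >= spec$dsc_floor) { done <- TRUE; break }
      fams <- lapply(fams, function(f) { f$levels <- f$levels * 0.8; f })
    }
    if (!done)
      stop("spec error: could not reach DSC floor ", spec$dsc_floor,
           " for tumor ", t, " (achieved ", round(dmin, 3), ")")
    tumors[[sprintf("tumor%02d", t)]] <- list(image = base$image, masks = masks)
  }
  cohort(tumors, provenance = sprintf("phantom cohort, seed %d", spec$seed))
}

#' Planted family assignment of a phantom spec
#'
#' @param spec A [phantom_spec()].
#' @return Named integer vector mapping segmentation id to family index.
#' @export
planted_families <- function(spec) {
  out <- integer(0)
  for (fi in seq_along(spec$families)) {
    fam <- spec$families[[fi]]
    fname <- names(spec$families)[fi]
    if (is.null(fname) || fname == "") fname <- paste0("f", fi)
    for (si in seq_along(fam$levels)) out[paste0(fname, "_", si)] <- fi
  }
  out
}
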