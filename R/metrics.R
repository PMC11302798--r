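# Geometric overlap metrics for pairs of masks on a shared grid. The
# boundary surface of a mask is the set of foreground voxels with at least
# one 6-connected background (or out-of-grid) neighbor; surface-to-surface
# distances are Euclidean distances between voxel centers in physical mm,
# computed with an exact distance transform.

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` over foreground voxel sets.
#'
#' @param a,b Aligned [label_mask()]s; at least one nonempty.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  assert_aligned(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) stop("dice undefined: both masks empty")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

.boundary_distances <- function(a, b) {
  # for each boundary voxel of a: distance (mm) to nearest boundary voxel of b
  ba <- cpp_boundary(a$voxels)
  bb <- cpp_boundary(b$voxels)
  db <- cpp_edt(bb, a$spacing)
  list(a_to_b = db[ba == 1L], n_a = sum(ba))
}

#' Surface Dice coefficient at a distance tolerance
#'
#' Fraction of the two boundary surfaces lying within `tolerance_mm` of the
#' other surface:
#' `(|S_A near S_B| + |S_B near S_A|) / (|S_A| + |S_B|)`, with surface
#' elements counted as boundary voxels and distances between voxel centers.
#' Symmetric in its arguments and nondecreasing in the tolerance.
#'
#' @param a,b Aligned nonempty [label_mask()]s.
#' @param tolerance_mm Positive distance tolerance in mm.
#' @return sDSC in `[0, 1]`.
#' @export
surface_dice <- function(a, b, tolerance_mm = 2) {
  assert_aligned(a, b)
  if (tolerance_mm <= 0) stop("config error: tolerance_mm must be positive")
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0)
    stop("surface_dice undefined for empty masks")
  ab <- .boundary_distances(a, b)
  ba <- .boundary_distances(b, a)
  tol <- tolerance_mm + 1e-9
  (sum(ab$a_to_b <= tol) + sum(ba$a_to_b <= tol)) / (ab$n_a + ba$n_a)
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric maximum Hausdorff distance between boundary voxel centers in
#' physical mm: `max(max_{p in S_A} min_{q in S_B} d(p,q), swap)`.
#'
#' @param a,b Aligned nonempty [label_mask()]s.
#' @return Distance in mm (0 iff the boundary voxel sets coincide).
#' @export
hausdorff <- function(a, b) {
  assert_aligned(a, b)
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0)
    stop("hausdorff undefined for empty masks")
  ab <- .boundary_distances(a, b)
  ba <- .boundary_distances(b, a)
  max(max(ab$a_to_b), max(ba$a_to_b))
}

#' All pairwise overlap metrics for one tumor's segmentations
#'
#' One row per unordered segmentation pair (k segmentations give
#' `choose(k, 2)` rows; 9 give 36).
#'
#' @param masks Named list of aligned nonempty [label_mask()]s.
#' @param tolerance_mm sDSC tolerance in mm (default 2, one voxel at the
#'   default resampled spacing).
#' @param tumor_id Identifier copied into the output.
#' @return data.frame with columns `tumor_id`, `seg_i`, `seg_j`, `dsc`,
#'   `sdsc`, `hd_mm`, `tolerance_mm`.
#' @export
pairwise_metrics <- function(masks, tolerance_mm = 2, tumor_id = "tumor") {
  ids <- names(masks)
  k <- length(ids)
  if (k < 2) stop("need at least 2 masks")
  if (tolerance_mm <= 0) stop("config error: tolerance_mm must be positive")
  for (i in seq_len(k - 1)) assert_aligned(masks[[i]], masks[[i + 1]])
  # per-mask caches: foreground count, boundary voxels, boundary EDT
  counts <- vapply(masks, function(m) sum(m$voxels), numeric(1))
  if (any(counts == 0)) stop("pairwise metrics need nonempty masks")
  bnds <- lapply(masks, function(m) cpp_boundary(m$voxels))
  edts <- lapply(bnds, function(b) cpp_edt(b, masks[[1]]$spacing))
  tol <- tolerance_mm + 1e-9
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      inter <- sum(masks[[i]]$voxels & masks[[j]]$voxels)
      d_ij <- edts[[j]][bnds[[i]] == 1L]  # surface i -> nearest surface j
      d_ji <- edts[[i]][bnds[[j]] == 1L]
      rows[[length(rows) + 1]] <- data.frame(
        tumor_id = tumor_id, seg_i = ids[i], seg_j = ids[j],
        dsc = 2 * inter / (counts[i] + counts[j]),
        sdsc = (sum(d_ij <= tol) + sum(d_ji <= tol)) / (length(d_ij) + length(d_ji)),
        hd_mm = max(max(d_ij), max(d_ji)),
        tolerance_mm = tolerance_mm,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise overlap metrics for a whole cohort
#'
#' Metrics are computed on the resampled grid, consistent with feature
#' extraction (pass `resample = FALSE` to use the native grid).
#'
#' @param x A [cohort()].
#' @param tolerance_mm sDSC tolerance in mm.
#' @param config [filter_config()] providing the resampling target.
#' @param resample Resample masks before measuring (default `TRUE`).
#' @return data.frame as in [pairwise_metrics()], all tumors stacked
#'   (10 tumors x 9 segmentations give 360 rows).
#' @export
cohort_metrics <- function(x, tolerance_mm = 2, config = filter_config(),
                           resample = TRUE) {
  rows <- list()
  for (tid in names(x$tumors)) {
    tm <- x$tumors[[tid]]
    masks <- tm$masks
    if (resample) {
      masks <- lapply(masks, function(m) {
        radagree::resample(tm$image, m, config)$mask
      })
    }
    rows[[length(rows) + 1]] <- pairwise_metrics(masks, tolerance_mm, tid)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
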