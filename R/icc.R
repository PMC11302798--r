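# Two-way ANOVA decomposition and the single-measure absolute-agreement
# intraclass correlation, ICC(A,1) in the McGraw & Wong (1996) taxonomy.
# The point estimate is identical under random- and mixed-rater assumptions;
# only its interpretation differs. Confidence bounds use the F-based
# interval with Satterthwaite degrees of freedom.

#' Two-way ANOVA mean squares of a complete rating matrix
#'
#' Decomposes an n subjects x k raters matrix into between-subject (`MSR`),
#' between-rater (`MSC`) and residual (`MSE`) mean squares. The sums of
#' squares satisfy `SS_total = SS_rows + SS_cols + SS_err`.
#'
#' @param m Numeric matrix, n >= 2 rows (subjects), k >= 2 columns (raters),
#'   no missing cells.
#' @return List with `MSR`, `MSC`, `MSE`, `n`, `k` and degrees of freedom.
#' @export
two_way_anova <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("rating matrix must be at least 2 x 2")
  if (anyNA(m) || any(!is.finite(m))) stop("rating matrix has missing/non-finite cells")
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  SSE <- sum(resid^2)
  list(MSR = SSR / (n - 1), MSC = SSC / (k - 1), MSE = SSE / ((n - 1) * (k - 1)),
       n = n, k = k,
       df_rows = n - 1, df_cols = k - 1, df_err = (n - 1) * (k - 1))
}

#' Single-measure absolute-agreement ICC with 95% bounds
#'
#' Computes ICC(A,1):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`,
#' with the F-based confidence interval using Satterthwaite degrees of
#' freedom evaluated at the point estimate. The estimate can be negative and
#' is never clamped. A matrix with no variance at all (constant) yields a
#' degenerate result with `icc = NA` and `degenerate = TRUE`.
#'
#' @param m Rating matrix (subjects x raters), see [two_way_anova()].
#' @param alpha Two-sided confidence level complement (default 0.05).
#' @return An `icc_result`: list with `icc`, `lower`, `upper`, `alpha`,
#'   `n`, `k`, the mean squares, `degenerate`, and a `model` tag.
#' @export
icc_absolute_agreement <- function(m, alpha = 0.05) {
  ms <- two_way_anova(m)
  MSR <- ms$MSR; MSC <- ms$MSC; MSE <- ms$MSE
  n <- ms$n; k <- ms$k
  out <- list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
              alpha = alpha, n = n, k = k,
              MSR = MSR, MSC = MSC, MSE = MSE,
              degenerate = FALSE,
              model = "A-1 two-way mixed, absolute agreement")
  class(out) <- "icc_result"
  if (MSR <= 0 && MSC <= 0 && MSE <= 0) {
    out$degenerate <- TRUE
    return(out)
  }
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  icc <- (MSR - MSE) / denom
  # Satterthwaite df for the composite denominator mean square
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0) v <- (n - 1) * (k - 1)
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  out$icc <- icc
  out$lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  out$upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  out
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<icc_result> degenerate (no variance), n =", x$n, "k =", x$k, "\n")
  } else {
    cat(sprintf("<icc_result> ICC(A,1) = %.4f [%.4f, %.4f], n = %d, k = %d\n",
                x$icc, x$lower, x$upper, x$n, x$k))
  }
  invisible(x)
}

#' ICC* of one feature: all tumors x all segmentations jointly
#'
#' Builds the n x k rating matrix (subjects = tumors, raters =
#' segmentations) for the feature and returns its [icc_absolute_agreement()].
#'
#' @param table A feature table from [extract_cohort()].
#' @param feature Feature identifier (row of [feature_ids()]).
#' @param alpha Confidence level complement.
#' @return An `icc_result`.
#' @export
icc_star <- function(table, feature, alpha = 0.05) {
  icc_absolute_agreement(feature_matrix(table, feature), alpha)
}

#' Pairwise ICCs of one feature: one per unordered segmentation pair
#'
#' For each unordered pair of segmentations an n x 2 rating matrix over the
#' tumors is scored (k = 9 segmentations give 36 pairs), plus the mean and
#' minimum of the pairwise estimates.
#'
#' @inheritParams icc_star
#' @return List with `pairs` (data.frame `seg_i`, `seg_j`, `icc`, `lower`,
#'   `upper`, `degenerate`), `icc_average` and `icc_min` over non-degenerate
#'   pairs.
#' @export
pairwise_icc <- function(table, feature, alpha = 0.05) {
  m <- feature_matrix(table, feature)
  segs <- colnames(m)
  k <- length(segs)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      r <- icc_absolute_agreement(m[, c(i, j)], alpha)
      rows[[length(rows) + 1]] <- data.frame(
        seg_i = segs[i], seg_j = segs[j],
        icc = r$icc, lower = r$lower, upper = r$upper,
        degenerate = r$degenerate, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  ok <- !pairs$degenerate
  list(pairs = pairs,
       icc_average = if (any(ok)) mean(pairs$icc[ok]) else NA_real_,
       icc_min = if (any(ok)) min(pairs$icc[ok]) else NA_real_)
}
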