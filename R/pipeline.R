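# End-to-end analysis: ICC* screening and feature selection, pairwise-ICC
# agreement maps, class discovery among segmentations, reference-based
# rating, and the metric-comparison report. Everything here is a
# deterministic function of the feature table and metric table.

#' Screen the feature panel by ICC*
#'
#' Computes ICC* for every feature, drops degenerate ones (no variance), and
#' selects the `n_select` lowest-ICC* features inside the band
#' `[band[1], band[2]]` — the low-reproducibility features most sensitive to
#' segmentation differences.
#'
#' @param table A feature table from [extract_cohort()].
#' @param band Inclusive ICC* band of interest (default `c(0.1, 0.51)`).
#' @param n_select Number of features to select from the band (default 10).
#' @param select Optional explicit selection: a data.frame of feature ids
#'   overriding the default lowest-ICC* rule.
#' @return A `selection_report`: list with `icc_star` (data.frame of all
#'   features and their ICC* + bounds), `degenerate` (excluded features),
#'   `band`, `in_band`, `selected` (data.frames of feature ids + ICC*), and
#'   `selection_rule`.
#' @export
screen_features <- function(table, band = c(0.1, 0.51), n_select = 10,
                            select = NULL) {
  ids <- feature_ids(table)
  res <- vector("list", nrow(ids))
  for (r in seq_len(nrow(ids))) {
    ic <- icc_star(table, ids[r, ])
    res[[r]] <- data.frame(ids[r, ], icc_star = ic$icc, lower = ic$lower,
                           upper = ic$upper, degenerate = ic$degenerate,
                           stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, res)
  rownames(all) <- NULL
  ok <- all[!all$degenerate, ]
  in_band <- ok[ok$icc_star >= band[1] & ok$icc_star <= band[2], ]
  if (nrow(in_band) == 0)
    warning("no feature has ICC* inside [", band[1], ", ", band[2], "]")
  if (is.null(select)) {
    sel <- in_band[order(in_band$icc_star), ]
    sel <- sel[seq_len(min(n_select, nrow(sel))), ]
    rule <- sprintf("lowest-%d ICC* within band", n_select)
  } else {
    key_all <- paste(all$image_type, all$feature_class, all$feature_name)
    key_sel <- paste(select$image_type, select$feature_class, select$feature_name)
    if (!all(key_sel %in% key_all))
      stop("explicit selection names unknown features")
    sel <- all[key_all %in% key_sel, ]
    rule <- "explicit list"
  }
  structure(list(icc_star = all, degenerate = all[all$degenerate, ],
                 band = band, in_band = in_band, selected = sel,
                 selection_rule = rule),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> ", nrow(x$icc_star), " features; ",
      nrow(x$in_band), " in ICC* band [", x$band[1], ", ", x$band[2],
      "]; ", nrow(x$selected), " selected (", x$selection_rule, ")\n", sep = "")
  invisible(x)
}

#' Pairwise-ICC agreement map for the selected features
#'
#' For every selected feature, a k x k symmetric matrix of pairwise ICCs
#' (diagonal 1 by convention); also the element-wise mean matrix across
#' features that drives class discovery.
#'
#' @param table A feature table.
#' @param selected data.frame of feature ids (e.g. `$selected` of
#'   [screen_features()]).
#' @return An `agreement_map`: list with `per_feature` (named list of k x k
#'   matrices), `mean` (k x k matrix), `segmentation_ids`.
#' @export
build_agreement_map <- function(table, selected) {
  if (nrow(selected) < 1) stop("selected feature set is empty")
  segs <- unique(table$segmentation_id)
  k <- length(segs)
  mats <- list()
  for (r in seq_len(nrow(selected))) {
    fid <- selected[r, ]
    pw <- pairwise_icc(table, fid)
    m <- matrix(NA_real_, k, k, dimnames = list(segs, segs))
    diag(m) <- 1
    for (q in seq_len(nrow(pw$pairs))) {
      i <- pw$pairs$seg_i[q]; j <- pw$pairs$seg_j[q]
      v <- if (pw$pairs$degenerate[q]) NA_real_ else pw$pairs$icc[q]
      m[i, j] <- v; m[j, i] <- v
    }
    mats[[paste(fid$image_type, fid$feature_class, fid$feature_name)]] <- m
  }
  mean_m <- Reduce(`+`, lapply(mats, function(m) {
    m[is.na(m)] <- 0; m
  })) / length(mats)
  structure(list(per_feature = mats, mean = mean_m, segmentation_ids = segs),
            class = "agreement_map")
}

#' Discover segmentation classes from an agreement map
#'
#' Average-linkage hierarchical clustering on the distance `1 - mean ICC`
#' (ICC floored at -1, so distances lie in `[0, 2]`), cut to `n_classes`.
#' With `n_classes = "auto"` the cut (2 to k-1 classes) maximizing the mean
#' silhouette width is chosen. Deterministic given the map.
#'
#' @param map An [build_agreement_map()] result.
#' @param n_classes Integer number of classes, or `"auto"`.
#' @return Named integer vector: class label per segmentation id.
#' @export
discover_classes <- function(map, n_classes = 3) {
  k <- length(map$segmentation_ids)
  m <- pmax(map$mean, -1)
  d <- 1 - m
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  if (identical(n_classes, "auto")) {
    best <- NULL; best_s <- -Inf
    for (g in 2:(k - 1)) {
      cl <- cutree(hc, g)
      s <- .mean_silhouette(d, cl)
      if (s > best_s) { best_s <- s; best <- cl }
    }
    return(best)
  }
  n_classes <- as.integer(n_classes)
  if (n_classes > k) stop("config error: n_classes exceeds the number of segmentations")
  if (n_classes < 1) stop("config error: n_classes must be >= 1")
  cutree(hc, n_classes)
}

.mean_silhouette <- function(d, cl) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]; own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }  # singleton clusters score 0
    a <- mean(d[i, own])
    bs <- vapply(setdiff(unique(cl), cl[i]),
                 function(g) mean(d[i, cl == g]), numeric(1))
    b <- if (length(bs)) min(bs) else NA_real_
    s[i] <- if (is.na(b) || max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Rate segmentations against a reference segmentation
#'
#' For each non-reference segmentation, collects the pairwise ICC versus the
#' reference across the selected features and issues a verdict:
#' `"discordant"` when all (rule `"all"`) or the median of (rule `"median"`)
#' the ICCs fall below `threshold`, `"concordant"` otherwise.
#'
#' @param table A feature table.
#' @param selected data.frame of selected feature ids.
#' @param reference_id Segmentation id used as the gold standard.
#' @param threshold ICC threshold (default 0.5).
#' @param rule `"all"` (default) or `"median"`.
#' @return List with `icc` (features x segmentations data.frame of ICC vs
#'   reference) and `verdicts` (named character vector).
#' @export
rate_against_reference <- function(table, selected, reference_id,
                                   threshold = 0.5, rule = c("all", "median")) {
  rule <- match.arg(rule)
  segs <- unique(table$segmentation_id)
  if (!reference_id %in% segs) stop("unknown reference segmentation: ", reference_id)
  others <- setdiff(segs, reference_id)
  rows <- list()
  dropped <- character()
  for (r in seq_len(nrow(selected))) {
    fid <- selected[r, ]
    m <- feature_matrix(table, fid)
    vals <- vapply(others, function(s) {
      res <- icc_absolute_agreement(m[, c(reference_id, s)])
      if (res$degenerate) NA_real_ else res$icc
    }, numeric(1))
    if (all(is.na(vals))) {
      dropped <- c(dropped, paste(fid$image_type, fid$feature_name))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      fid, t(vals), check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0)
    message("dropped degenerate features vs reference: ",
            paste(dropped, collapse = ", "))
  icc_df <- do.call(rbind, rows)
  rownames(icc_df) <- NULL
  verdicts <- vapply(others, function(s) {
    v <- icc_df[[s]]
    v <- v[!is.na(v)]
    bad <- switch(rule, all = all(v < threshold), median = median(v) < threshold)
    if (bad) "discordant" else "concordant"
  }, character(1))
  list(icc = icc_df, verdicts = verdicts, reference_id = reference_id,
       threshold = threshold, rule = rule)
}

#' Metric-comparison report: pairwise ICC versus DSC / sDSC / HD
#'
#' Averages the geometric metrics over tumors (36 values per metric for
#' k = 9), joins them with the per-feature pairwise ICCs of the agreement
#' map, and summarizes the per-metric and per-feature ranges — the scatter
#' data contrasting the ICC spread against the narrow DSC/sDSC range.
#'
#' @param map An [build_agreement_map()] result.
#' @param metrics A pair-metric table from [cohort_metrics()].
#' @return List with `scatter` (long data.frame: pair, feature, icc, dsc,
#'   sdsc, hd_mm), `pair_means` (one row per pair with tumor-averaged
#'   metrics and mean ICC), and `ranges` (summary list).
#' @export
metric_comparison_report <- function(map, metrics) {
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")
  metrics$pair <- pair_key(metrics$seg_i, metrics$seg_j)
  agg <- aggregate(metrics[, c("dsc", "sdsc", "hd_mm")],
                   by = list(pair = metrics$pair), FUN = mean)
  segs <- map$segmentation_ids
  k <- length(segs)
  map_pairs <- character(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    map_pairs <- c(map_pairs, pair_key(segs[i], segs[j]))
  missing <- setdiff(map_pairs, agg$pair)
  if (length(missing) > 0)
    stop("join error: metric table lacks pairs: ", paste(missing, collapse = ", "))
  rows <- list()
  for (feat in names(map$per_feature)) {
    m <- map$per_feature[[feat]]
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      key <- pair_key(segs[i], segs[j])
      a <- agg[agg$pair == key, ]
      rows[[length(rows) + 1]] <- data.frame(
        pair = key, feature = feat, icc = m[segs[i], segs[j]],
        dsc = a$dsc, sdsc = a$sdsc, hd_mm = a$hd_mm,
        stringsAsFactors = FALSE)
    }
  }
  scatter <- do.call(rbind, rows)
  rownames(scatter) <- NULL
  mean_icc <- aggregate(scatter$icc, by = list(pair = scatter$pair),
                        FUN = mean, na.rm = TRUE)
  names(mean_icc)[2] <- "mean_icc"
  pair_means <- merge(agg, mean_icc, by = "pair")
  per_feat_range <- do.call(rbind, lapply(names(map$per_feature), function(f) {
    v <- scatter$icc[scatter$feature == f]
    data.frame(feature = f, icc_min = min(v, na.rm = TRUE),
               icc_max = max(v, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  ranges <- list(
    icc_per_feature = per_feat_range,
    icc_min = min(scatter$icc, na.rm = TRUE),
    icc_max = max(scatter$icc, na.rm = TRUE),
    dsc_min = min(agg$dsc), sdsc_min = min(agg$sdsc), hd_max = max(agg$hd_mm))
  list(scatter = scatter, pair_means = pair_means, ranges = ranges)
}
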