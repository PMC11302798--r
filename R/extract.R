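# Panel assembly: resample once, derive the image-type bank, then per image
# type discretize and compute the 93 non-shape features; the 14 shape
# features are computed once on the resampled original mask. Under the
# default configuration the panel has 93 x 10 + 14 = 944 features.
#
# Filtered images depend only on the image, not on the mask, so cohort
# extraction derives the image bank once per tumor and reuses it for every
# segmentation.

.feature_classes_nonshape <- c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")

.class_features <- function(cls, image, mask, droi) {
  switch(cls,
    firstorder = first_order_features(image, mask, droi),
    glcm = glcm_features(droi),
    glrlm = glrlm_features(droi),
    glszm = glszm_features(droi),
    gldm = gldm_features(droi),
    ngtdm = ngtdm_features(droi))
}

# feature rows for one (derived image bank, resampled mask); `wanted` is a
# data.frame(image_type, feature_class) of the combinations to compute
.extract_rows <- function(derived, mask, bin_width, wanted) {
  rows <- list()
  for (lab in unique(wanted$image_type[wanted$feature_class != "shape"])) {
    droi <- tryCatch(
      discretize(derived[[lab]], mask, bin_width),
      error = function(e) stop("image_type ", lab, ": ", conditionMessage(e)))
    for (cls in wanted$feature_class[wanted$image_type == lab]) {
      if (cls == "shape") next
      v <- .class_features(cls, derived[[lab]], mask, droi)
      rows[[length(rows) + 1]] <- data.frame(
        image_type = lab, feature_class = cls,
        feature_name = names(v), value = unname(v), stringsAsFactors = FALSE)
    }
  }
  if (any(wanted$feature_class == "shape")) {
    v <- shape_features(mask)
    rows[[length(rows) + 1]] <- data.frame(
      image_type = "original", feature_class = "shape",
      feature_name = names(v), value = unname(v), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.wanted_combinations <- function(config, types, classes, features) {
  all_types <- image_types(config)
  if (!is.null(features)) {
    w <- unique(features[, c("image_type", "feature_class")])
  } else {
    if (is.null(types)) types <- all_types
    if (is.null(classes)) classes <- c(.feature_classes_nonshape, "shape")
    w <- expand.grid(image_type = types,
                     feature_class = intersect(classes, .feature_classes_nonshape),
                     stringsAsFactors = FALSE)
    if ("shape" %in% classes && "original" %in% types)
      w <- rbind(w, data.frame(image_type = "original", feature_class = "shape"))
  }
  unknown <- setdiff(w$image_type, all_types)
  if (length(unknown) > 0)
    stop("unknown image type(s): ", paste(unknown, collapse = ", "))
  bad <- w$feature_class == "shape" & w$image_type != "original"
  if (any(bad)) stop("shape features exist only on the original image type")
  w
}

.resample_mask_to <- function(mask, grid) {
  mvox <- cpp_resample_nearest(array(as.double(mask$voxels), dim(mask$voxels)),
                               mask$spacing, mask$origin,
                               grid$dim, grid$spacing, grid$origin)
  mvox <- array(as.integer(mvox >= 0.5), grid$dim)
  if (sum(mvox) < 1)
    stop("degenerate-ROI error: mask became empty after resampling")
  label_mask(mvox, grid$spacing, grid$origin)
}

#' Extract the radiomics feature panel for one image/mask pair
#'
#' Resamples image and mask to the configured spacing, derives the image-type
#' bank (original, LoG, 8 wavelet sub-bands), discretizes each derived image
#' over the ROI with the fixed bin width (bin origin = per-type ROI minimum),
#' and computes 18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
#' 5 NGTDM features per image type, plus 14 shape features on the resampled
#' original mask: 944 features under the defaults.
#'
#' @param image An [image_volume()].
#' @param mask A nonempty [label_mask()] aligned with `image`.
#' @param config A [filter_config()].
#' @param bin_width Fixed discretization bin width (default 25).
#' @param types Optional restriction of image types (see [image_types()]);
#'   shape features are emitted only when `"original"` is included.
#' @param classes Optional restriction of feature classes.
#' @param features Optional data.frame of feature ids (`image_type`,
#'   `feature_class`, `feature_name`): compute only what these need and
#'   return only these rows.
#' @return A data.frame with columns `image_type`, `feature_class`,
#'   `feature_name`, `value`.
#' @export
extract_all <- function(image, mask, config = filter_config(), bin_width = 25,
                        types = NULL, classes = NULL, features = NULL) {
  if (n_foreground(mask) < 1) stop("degenerate-ROI error: empty mask")
  wanted <- .wanted_combinations(config, types, classes, features)
  res <- resample(image, mask, config)
  derived <- derive_images(res$image, config,
                           types = setdiff(unique(wanted$image_type), NA))
  out <- .extract_rows(derived, res$mask, bin_width, wanted)
  if (!is.null(features)) out <- .filter_features(out, features)
  out
}

.filter_features <- function(rows, features) {
  key <- paste(rows$image_type, rows$feature_class, rows$feature_name)
  want <- paste(features$image_type, features$feature_class, features$feature_name)
  out <- rows[key %in% want, ]
  rownames(out) <- NULL
  out
}

#' Extract the feature panel for every tumor/segmentation of a cohort
#'
#' The filtered image bank is derived once per tumor and shared across its
#' segmentations.
#'
#' @param x A [cohort()].
#' @inheritParams extract_all
#' @param verbose Print progress per tumor.
#' @return A feature table: data.frame with columns `tumor_id`,
#'   `segmentation_id`, `image_type`, `feature_class`, `feature_name`,
#'   `value` (rectangular over tumors x segmentations x features).
#' @export
extract_cohort <- function(x, config = filter_config(), bin_width = 25,
                           types = NULL, classes = NULL, features = NULL,
                           verbose = FALSE) {
  wanted <- .wanted_combinations(config, types, classes, features)
  rows <- list()
  for (tid in names(x$tumors)) {
    if (verbose) message("extracting tumor ", tid)
    tm <- x$tumors[[tid]]
    sp <- config$resample_spacing_mm
    g <- .resample_grid(dim(tm$image$voxels), tm$image$spacing, tm$image$origin, sp)
    grid <- list(dim = g$dim, spacing = sp, origin = g$origin)
    vox <- cpp_resample_trilinear(tm$image$voxels, tm$image$spacing,
                                  tm$image$origin, g$dim, sp, g$origin)
    res_image <- image_volume(vox, sp, g$origin)
    derived <- derive_images(res_image, config,
                             types = unique(wanted$image_type))
    for (sid in names(tm$masks)) {
      assert_aligned(tm$image, tm$masks[[sid]])
      res_mask <- .resample_mask_to(tm$masks[[sid]], grid)
      fv <- .extract_rows(derived, res_mask, bin_width, wanted)
      if (!is.null(features)) fv <- .filter_features(fv, features)
      fv <- cbind(data.frame(tumor_id = tid, segmentation_id = sid,
                             stringsAsFactors = FALSE), fv)
      rows[[length(rows) + 1]] <- fv
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.feature_key <- function(table) {
  paste(table$image_type, table$feature_class, table$feature_name, sep = "|")
}

#' Unique feature identifiers of a feature table
#' @param table A feature table from [extract_cohort()].
#' @return data.frame with `image_type`, `feature_class`, `feature_name`.
#' @export
feature_ids <- function(table) {
  out <- unique(table[, c("image_type", "feature_class", "feature_name")])
  rownames(out) <- NULL
  out
}

#' Rating matrix (tumors x segmentations) for one feature
#'
#' @param table A feature table from [extract_cohort()].
#' @param feature A one-row data.frame (or list) with `image_type`,
#'   `feature_class`, `feature_name`.
#' @return Numeric matrix, rows = tumors, columns = segmentations.
#' @export
feature_matrix <- function(table, feature) {
  sel <- table$image_type == feature$image_type &
    table$feature_class == feature$feature_class &
    table$feature_name == feature$feature_name
  sub <- table[sel, ]
  tumors <- unique(table$tumor_id)
  segs <- unique(table$segmentation_id)
  m <- matrix(NA_real_, length(tumors), length(segs),
              dimnames = list(tumors, segs))
  m[cbind(match(sub$tumor_id, tumors), match(sub$segmentation_id, segs))] <- sub$value
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("completeness error: feature ", feature$feature_name,
         " missing for tumor ", tumors[miss[1, 1]],
         ", segmentation ", segs[miss[1, 2]])
  }
  m
}

#' Write / read a tidy feature table CSV
#'
#' Columns: `tumor_id`, `segmentation_id`, `image_type`, `feature_class`,
#' `feature_name`, `value`.
#'
#' @param table A feature table.
#' @param path CSV path.
#' @return The path (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(tumor_id = "character",
                          segmentation_id = "character"))
}
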