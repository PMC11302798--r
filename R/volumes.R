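#' @useDynLib radagree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile sd var qf hclust cutree as.dist median rnorm runif aggregate cov
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Containers
#
# An image_volume is a 3-D scalar grid with a physical geometry:
#   voxels  -- 3-D numeric array, first index fastest (R layout)
#   spacing -- per-axis voxel size in mm
#   origin  -- physical position (mm) of voxel (1,1,1)'s center
# A voxel at 1-based index (i,j,k) sits at origin + (i-1, j-1, k-1) * spacing.
# Only axis-aligned geometries are supported; a label_mask is the same thing
# with voxels restricted to {0, 1}.
# ---------------------------------------------------------------------------

#' Create an image volume
#'
#' @param voxels 3-D numeric array of scalar intensities.
#' @param spacing Per-axis physical voxel size in mm (length 3, all > 0).
#' @param origin Physical coordinate (mm) of the center of voxel (1,1,1).
#' @return An `image_volume` object.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(dim(voxels) < 1L)) stop("grid needs at least one voxel per axis")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Create a binary label mask
#'
#' @param voxels 3-D array containing only 0 and 1 (logical accepted).
#' @inheritParams image_volume
#' @return A `label_mask` object.
#' @export
label_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (is.logical(voxels)) voxels[] <- as.integer(voxels)
  rng <- range(voxels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1 ||
      any(voxels != as.integer(voxels)))
    stop("mask voxels must be 0 or 1")
  storage.mode(voxels) <- "integer"
  vol <- image_volume(array(0, dim(voxels)), spacing, origin)
  structure(list(voxels = voxels, spacing = vol$spacing, origin = vol$origin),
            class = "label_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " foreground, spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

n_foreground <- function(mask) sum(mask$voxels)

#' Check that an image and a mask live on the same grid
#'
#' Passes when shapes are equal and spacing and origin agree within `tol_mm`;
#' otherwise raises an error naming the offending field.
#'
#' @param image,mask Objects with `voxels`, `spacing`, `origin`.
#' @param tol_mm Geometric tolerance in mm.
#' @return Invisibly `TRUE` on success.
#' @export
assert_aligned <- function(image, mask, tol_mm = 1e-3) {
  if (!identical(dim(image$voxels), dim(mask$voxels)))
    stop("alignment error: grid shapes differ (",
         paste(dim(image$voxels), collapse = "x"), " vs ",
         paste(dim(mask$voxels), collapse = "x"), ")")
  if (any(abs(image$spacing - mask$spacing) > tol_mm))
    stop("alignment error: spacing differs by more than ", tol_mm, " mm")
  if (any(abs(image$origin - mask$origin) > tol_mm))
    stop("alignment error: origin differs by more than ", tol_mm, " mm")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# NRRD I/O (detached-free, axis-aligned subset of NRRD0004)
# ---------------------------------------------------------------------------

.nrrd_types <- list(
  "double" = list(what = "double", size = 8),
  "float"  = list(what = "double", size = 4),
  "short"  = list(what = "integer", size = 2),
  "unsigned short" = list(what = "integer", size = 2, unsigned = TRUE),
  "ushort" = list(what = "integer", size = 2, unsigned = TRUE),
  "int"    = list(what = "integer", size = 4),
  "uint"   = list(what = "integer", size = 4),
  "uchar"  = list(what = "integer", size = 1, unsigned = TRUE),
  "unsigned char" = list(what = "integer", size = 1, unsigned = TRUE),
  "signed char" = list(what = "integer", size = 1),
  "char"   = list(what = "integer", size = 1)
)

.parse_nrrd_vectors <- function(txt) {
  # "(a,b,c) (d,e,f) ..." -> list of numeric vectors; "none" entries dropped
  m <- gregexpr("\\(([^)]*)\\)", txt)[[1]]
  if (m[1] == -1) return(list())
  lapply(regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]], function(s) {
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic)) stop("I/O error: ", path, " is not a NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("I/O error: truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stop("format error: NRRD missing field '", f, "' in ", path)
    fields[[f]]
  }
  dimn <- as.integer(need("dimension"))
  if (dimn != 3L) stop("format error: only 3-D NRRD supported (got dimension ", dimn, ")")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- tolower(need("type"))
  tinfo <- .nrrd_types[[type]]
  if (is.null(tinfo)) stop("format error: unsupported NRRD type '", type, "'")
  encoding <- tolower(if (is.null(fields$encoding)) "raw" else fields$encoding)
  endian <- tolower(if (is.null(fields$endian)) "little" else fields$endian)

  spacing <- NULL; origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    dirs <- .parse_nrrd_vectors(fields[["space directions"]])
    if (length(dirs) != 3) stop("format error: need 3 space directions")
    d <- do.call(rbind, dirs)
    offdiag <- d; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6 * max(abs(diag(d)))))
      stop("format error: oblique space directions are not supported")
    if (any(diag(d) <= 0))
      stop("format error: flipped axes are not supported")
    spacing <- diag(d)
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  if (is.null(spacing) || any(!is.finite(spacing)))
    stop("format error: NRRD in ", path, " carries no voxel spacing")
  if (!is.null(fields[["space origin"]])) {
    origin <- .parse_nrrd_vectors(fields[["space origin"]])[[1]]
  }

  n <- prod(sizes)
  if (encoding == "raw") {
    vals <- readBin(con, tinfo$what, n = n, size = tinfo$size, endian = endian,
                    signed = !isTRUE(tinfo$unsigned) || tinfo$size > 2)
  } else if (encoding %in% c("gzip", "gz")) {
    blob <- readBin(con, "raw", n = file.size(path))
    vals <- readBin(memDecompress(blob, type = "gzip"), tinfo$what, n = n,
                    size = tinfo$size, endian = endian,
                    signed = !isTRUE(tinfo$unsigned) || tinfo$size > 2)
  } else if (encoding %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else {
    stop("format error: unsupported NRRD encoding '", encoding, "'")
  }
  if (length(vals) < n) stop("I/O error: truncated NRRD data in ", path)
  list(voxels = array(as.double(vals), sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(voxels, spacing, origin, path, type = "double") {
  dims <- dim(voxels)
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dims, collapse = " ")),
    "space: left-posterior-superior",
    paste0("space directions: (", spacing[1], ",0,0) (0,", spacing[2],
           ",0) (0,0,", spacing[3], ")"),
    paste0("space origin: (", paste(origin, collapse = ","), ")"),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (type == "double") {
    writeBin(as.double(voxels), con, size = 8, endian = "little")
  } else if (type == "uchar") {
    writeBin(as.integer(voxels), con, size = 1, endian = "little")
  } else if (type == "short") {
    writeBin(as.integer(voxels), con, size = 2, endian = "little")
  } else stop("unsupported NRRD write type '", type, "'")
  invisible(path)
}

# ---------------------------------------------------------------------------
# NIfTI I/O (axis-aligned volumes through RNifti)
# ---------------------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("format error: only 3-D NIfTI supported: ", path)
  x <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  if (attr(x, "code") != 0) {
    rot <- x[1:3, 1:3]
    offd <- rot; diag(offd) <- 0
    if (any(abs(offd) > 1e-4 * max(abs(diag(rot)))))
      stop("format error: oblique NIfTI orientations are not supported: ", path)
    if (any(diag(rot) < 0))
      stop("format error: flipped NIfTI axes are not supported: ", path)
    spacing <- diag(rot)
    origin <- x[1:3, 4]
  }
  list(voxels = array(as.double(arr), dim(arr)), spacing = spacing, origin = origin)
}

write_nifti_volume <- function(voxels, spacing, origin, path) {
  img <- RNifti::asNifti(array(as.double(voxels), dim(voxels)))
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.sniff_format <- function(path, format = "auto") {
  if (format != "auto") return(format)
  lp <- tolower(path)
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  stop("cannot infer file format from extension: ", path)
}

#' Read a scalar volume from NRRD or NIfTI-1
#'
#' Spacing and origin are taken from the file header; voxel values are left
#' untouched beyond the format's stored slope/intercept. Oblique orientation
#' matrices are rejected: the toolkit only uses axis-aligned geometry.
#'
#' @param path Path to a `.nrrd`, `.nii` or `.nii.gz` file.
#' @param format One of `"auto"`, `"nrrd"`, `"nifti"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  format <- .sniff_format(path, format)
  raw <- switch(format, nrrd = read_nrrd(path), nifti = read_nifti_volume(path))
  image_volume(raw$voxels, raw$spacing, raw$origin)
}

#' Write a scalar volume
#'
#' @param volume An [image_volume()].
#' @param path Output path; `.nrrd` writes NRRD (raw little-endian doubles),
#'   `.nii`/`.nii.gz` writes NIfTI-1.
#' @param format One of `"auto"`, `"nrrd"`, `"nifti"`.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nrrd", "nifti")) {
  format <- .sniff_format(path, match.arg(format))
  switch(format,
    nrrd = write_nrrd(volume$voxels, volume$spacing, volume$origin, path, "double"),
    nifti = write_nifti_volume(volume$voxels, volume$spacing, volume$origin, path))
  invisible(path)
}

#' Read a binary mask from a label image
#'
#' Voxels equal to `positive_label` map to 1, everything else to 0. If the
#' label image is nonempty but never takes `positive_label`, a warning is
#' raised and an empty mask returned (callers decide whether to reject it).
#'
#' @param path Path to a NRRD or NIfTI label image.
#' @param positive_label Integer value coding the foreground.
#' @param format One of `"auto"`, `"nrrd"`, `"nifti"`.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, positive_label = 1, format = c("auto", "nrrd", "nifti")) {
  vol <- read_volume(path, format)
  vals <- unique(as.vector(vol$voxels))
  if (length(setdiff(vals, 0)) > 1 && missing(positive_label))
    stop("ambiguity error: multi-label image; pass positive_label explicitly: ", path)
  fg <- vol$voxels == positive_label
  if (!any(fg) && any(vol$voxels != 0))
    warning("positive_label ", positive_label, " absent from nonempty label image: ", path)
  label_mask(array(as.integer(fg), dim(vol$voxels)), vol$spacing, vol$origin)
}

#' Write a binary mask as a label image
#'
#' @param mask A [label_mask()].
#' @inheritParams write_volume
#' @export
write_mask <- function(mask, path, format = c("auto", "nrrd", "nifti")) {
  format <- .sniff_format(path, match.arg(format))
  switch(format,
    nrrd = write_nrrd(mask$voxels, mask$spacing, mask$origin, path, "uchar"),
    nifti = write_nifti_volume(mask$voxels, mask$spacing, mask$origin, path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cohorts
# ---------------------------------------------------------------------------

#' Assemble a cohort of tumors with multiple segmentations
#'
#' @param tumors Named list; each element is `list(image = image_volume,
#'   masks = named list of label_mask)`. Mask names (segmentation ids) must be
#'   identical across tumors; every mask must be aligned to its tumor's image.
#' @param provenance Optional free-text notes carried along.
#' @return A `cohort` object.
#' @export
cohort <- function(tumors, provenance = character()) {
  if (length(tumors) < 1) stop("a cohort needs at least one tumor")
  if (is.null(names(tumors)) || any(names(tumors) == ""))
    stop("tumors must be a named list (tumor ids)")
  seg_ids <- names(tumors[[1]]$masks)
  for (tid in names(tumors)) {
    tm <- tumors[[tid]]
    if (!identical(names(tm$masks), seg_ids))
      stop("segmentation ids differ for tumor ", tid,
           "; all tumors must carry the same ids in the same order")
    for (sid in seg_ids) assert_aligned(tm$image, tm$masks[[sid]])
  }
  structure(list(tumors = tumors, segmentation_ids = seg_ids,
                 provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$tumors), " tumors x ",
      length(x$segmentation_ids), " segmentations\n", sep = "")
  invisible(x)
}

#' Read a cohort from a manifest CSV
#'
#' The manifest has columns `tumor_id`, `image_path`, `segmentation_id`,
#' `mask_path` (one row per tumor/segmentation pair); relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param positive_label Foreground label passed to [read_mask()].
#' @return A [cohort()].
#' @export
read_cohort_manifest <- function(path, positive_label = 1) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tumor_id", "image_path", "segmentation_id", "mask_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  tumors <- list()
  for (tid in unique(man$tumor_id)) {
    rows <- man[man$tumor_id == tid, ]
    image <- read_volume(resolve(rows$image_path[1]))
    masks <- list()
    for (r in seq_len(nrow(rows))) {
      m <- read_mask(resolve(rows$mask_path[r]), positive_label)
      if (n_foreground(m) < 1)
        stop("empty mask for tumor ", tid, " segmentation ", rows$segmentation_id[r])
      masks[[as.character(rows$segmentation_id[r])]] <- m
    }
    tumors[[as.character(tid)]] <- list(image = image, masks = masks)
  }
  cohort(tumors, provenance = paste("manifest:", path))
}

#' Write a cohort to disk as NRRD volumes plus a manifest CSV
#'
#' @param x A [cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (tid in names(x$tumors)) {
    tm <- x$tumors[[tid]]
    ipath <- file.path(dir, paste0(tid, "_image.nrrd"))
    write_volume(tm$image, ipath)
    for (sid in names(tm$masks)) {
      mpath <- file.path(dir, paste0(tid, "_", sid, "_mask.nrrd"))
      write_mask(tm$masks[[sid]], mpath)
      rows[[length(rows) + 1]] <- data.frame(
        tumor_id = tid, image_path = basename(ipath),
        segmentation_id = sid, mask_path = basename(mpath))
    }
  }
  man <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(man, mpath, row.names = FALSE)
  invisible(mpath)
}
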