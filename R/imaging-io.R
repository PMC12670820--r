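#' Read an 8-bit RGB image
#'
#' Reads PNG or TIFF into an `H x W x 3` integer array in 0-255, row-major
#' with origin at the top-left. Grayscale images are promoted to RGB by
#' channel replication (with a warning); an alpha channel, if present, is
#' dropped with a warning. TIFFs with a bit depth other than 8 are
#' rejected.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return integer array `H x W x 3`, values 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (!is.null(bits) && !identical(as.integer(bits), 8L))
      stop("unsupported TIFF bit depth ", bits, " in ", path,
           "; expected 8-bit samples", call. = FALSE)
  } else {
    stop("unsupported image format '", ext, "' for ", path,
         "; expected PNG or TIFF", call. = FALSE)
  }
  if (length(dim(raw)) == 2L) {
    warning("grayscale image promoted to RGB by channel replication: ", path)
    raw <- array(raw, c(dim(raw), 3L))
  } else if (dim(raw)[3] == 2L) {
    warning("gray+alpha image: alpha dropped, gray replicated to RGB: ", path)
    raw <- array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  } else if (dim(raw)[3] == 4L) {
    warning("alpha channel dropped: ", path)
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (dim(raw)[3] != 3L) {
    stop("unsupported channel count ", dim(raw)[3], " in ", path, call. = FALSE)
  }
  img <- round(raw * 255)
  storage.mode(img) <- "integer"
  attributes(img) <- list(dim = dim(img))   # drop reader metadata
  img
}

#' Write an 8-bit RGB image
#'
#' @param img `H x W x 3` numeric array, values 0-255.
#' @param path destination `.png`, `.tif` or `.tiff`; format chosen by
#'   extension. TIFF is written uncompressed so the round trip is lossless.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (min(img) < 0 || max(img) > 255)
    stop("image values must lie in 0-255", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  dat <- round(img) / 255
  ok <- switch(ext,
    png  = png::writePNG(dat, path),
    tif  = ,
    tiff = tiff::writeTIFF(dat, path, bits.per.sample = 8L,
                           compression = "none"),
    stop("unsupported image format '", ext, "'", call. = FALSE))
  invisible(path)
}

#' Read / write a label mask
#'
#' Masks are stored as 8-bit single-channel PNG whose raw pixel values are
#' the class codes 0-5 (plus the unlabeled sentinel 255). This keeps the
#' file lossless, human-viewable and diff-able; [mask_to_rgb()] gives a
#' color rendering. The round trip `write_mask()` then `read_mask()` is the
#' identity.
#'
#' @param path PNG file path.
#' @param allow_unlabeled permit the training sentinel 255 on read.
#' @return integer matrix of class codes.
#' @export
read_mask <- function(path, allow_unlabeled = TRUE) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  mask <- round(raw * 255)
  storage.mode(mask) <- "integer"
  assert_label_mask(mask, allow_unlabeled = allow_unlabeled,
                    what = paste0("mask file ", path))
  mask
}

#' @rdname read_mask
#' @param mask integer matrix with values in 0-5 (and optionally 255).
#' @export
write_mask <- function(mask, path) {
  assert_label_mask(mask, allow_unlabeled = TRUE)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Construct a region-of-interest annotation
#'
#' ROIs carry the sparse expert annotations that train the pixel
#' classifier. Vertices are `(row, col)` pixel coordinates, 0-based with
#' origin at the top-left; a pixel belongs to the polygon when its center
#' lies inside under the even-odd rule with half-open boundaries.
#'
#' @param polygon numeric matrix with >= 3 rows and columns `(row, col)`.
#' @param label tissue class name (see [tissue_class_names()]); background
#'   ROIs are allowed.
#' @param id annotation identifier used in error messages.
#' @return object of class `nm_roi`.
#' @export
roi_annotation <- function(polygon, label, id = "roi") {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L)
    stop("ROI '", id, "' needs at least 3 vertices", call. = FALSE)
  if (ncol(polygon) != 2L)
    stop("ROI '", id, "' polygon must have two columns (row, col)",
         call. = FALSE)
  if (!label %in% tissue_class_names())
    stop("ROI '", id, "' has unknown label '", label, "'", call. = FALSE)
  structure(list(polygon = polygon, label = label, id = id),
            class = "nm_roi")
}

# internal: even-odd scanline containment test for pixel centers.
# Pixel (r, c) has its center at continuous coordinates (r, c); an edge is
# counted when it crosses the horizontal ray to the left of the center,
# using the half-open rule (y1 <= r) != (y2 <= r), so shared polygon edges
# never double-label a pixel.
polygon_fill <- function(polygon, shape) {
  H <- shape[1]; W <- shape[2]
  rmin <- max(0L, floor(min(polygon[, 1])))
  rmax <- min(H - 1L, ceiling(max(polygon[, 1])))
  cmin <- max(0L, floor(min(polygon[, 2])))
  cmax <- min(W - 1L, ceiling(max(polygon[, 2])))
  if (rmax < rmin || cmax < cmin) return(matrix(FALSE, H, W))
  inside <- matrix(FALSE, H, W)
  rows <- rmin:rmax
  cols <- cmin:cmax
  n <- nrow(polygon)
  y1 <- polygon[, 1]; x1 <- polygon[, 2]
  y2 <- polygon[c(2:n, 1), 1]; x2 <- polygon[c(2:n, 1), 2]
  for (r in rows) {
    crosses <- (y1 <= r) != (y2 <= r)
    if (!any(crosses)) next
    xin <- x1[crosses] + (r - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    # parity of crossings strictly to the right of each pixel center
    cnt <- vapply(cols, function(cc) sum(xin > cc), integer(1))
    inside[r + 1L, cols + 1L] <- (cnt %% 2L) == 1L
  }
  inside
}

#' Rasterize ROI annotations into a training mask
#'
#' Pixels inside a polygon receive its class label; pixels covered by no
#' ROI receive the unlabeled sentinel 255 and are excluded from training.
#' Overlapping ROIs are resolved last-listed-wins.
#'
#' @param rois list of [roi_annotation()] objects.
#' @param shape integer vector `c(H, W)`.
#' @return integer matrix `H x W` of class codes with 255 where unlabeled.
#' @export
rois_to_mask <- function(rois, shape) {
  stopifnot(length(shape) == 2L)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  mask <- matrix(MASK_UNLABELED, H, W)
  classes <- tissue_classes()
  for (roi in rois) {
    if (!inherits(roi, "nm_roi")) roi <- do.call(roi_annotation, roi)
    p <- roi$polygon
    if (any(p[, 1] < 0 | p[, 1] > H | p[, 2] < 0 | p[, 2] > W))
      stop("ROI '", roi$id, "' has out-of-bounds vertices for a ",
           H, "x", W, " canvas", call. = FALSE)
    sel <- polygon_fill(p, c(H, W))
    mask[sel] <- classes[[roi$label]]
  }
  mask
}

#' Read and validate a cohort metadata table
#'
#' Expects a CSV with columns `sample_id, group, nrs, age, sex, mpp`.
#' Group values are matched case-insensitively against
#' `control`, `nonpainful_neuroma`, `painful_neuroma`. Validation failures
#' are reported with the offending row numbers.
#'
#' @param path CSV file.
#' @return data.frame of validated cohort records.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "nrs", "age", "sex", "mpp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  validate_cohort_records(df)
}

#' @rdname read_cohort_table
#' @param df data.frame of cohort records to validate in place.
#' @export
validate_cohort_records <- function(df) {
  groups <- c("control", "nonpainful_neuroma", "painful_neuroma")
  g <- tolower(trimws(df$group))
  errs <- character(0)
  bad_g <- which(!g %in% groups)
  if (length(bad_g))
    errs <- c(errs, paste0("row ", bad_g, ": unknown group '",
                           df$group[bad_g], "'"))
  nrs <- suppressWarnings(as.numeric(df$nrs))
  bad_n <- which(is.na(nrs) | nrs < 0 | nrs > 10 | nrs != round(nrs))
  if (length(bad_n))
    errs <- c(errs, paste0("row ", bad_n, ": NRS '", df$nrs[bad_n],
                           "' outside integer 0-10"))
  mpp <- suppressWarnings(as.numeric(df$mpp))
  bad_m <- which(is.na(mpp) | mpp <= 0)
  if (length(bad_m))
    errs <- c(errs, paste0("row ", bad_m, ": nonpositive mpp '",
                           df$mpp[bad_m], "'"))
  zero_req <- which(g %in% c("control", "nonpainful_neuroma") &
                      !is.na(nrs) & nrs != 0)
  if (length(zero_req))
    errs <- c(errs, paste0("row ", zero_req,
                           ": control/non-painful samples must have NRS 0"))
  if (length(errs))
    stop("invalid cohort records:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  df$group <- g
  df$nrs <- as.integer(nrs)
  df$mpp <- mpp
  df$sex <- tolower(trimws(df$sex))
  df
}

#' Write per-sample compositions and a statistics report to disk
#'
#' Compositions go to TSV (one row per sample, stable column order);
#' the analysis report goes to pretty-printed JSON.
#'
#' @param compositions data.frame from [quantify_composition()] /
#'   [composition_table()].
#' @param report `nm_report` from [run_full_analysis()], or `NULL`.
#' @param dir output directory, created if needed.
#' @return named list of the files written, invisibly.
#' @export
write_results <- function(compositions, report = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "compositions.tsv")
  utils::write.table(compositions, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- list(compositions = tsv)
  if (!is.null(report)) {
    js <- file.path(dir, "stats_report.json")
    jsonlite::write_json(unclass(report), js, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    out$report <- js
  }
  invisible(out)
}
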