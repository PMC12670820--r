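#' Tissue class vocabulary
#'
#' The package segments nerve cross-sections into six classes: background
#' plus the five tissue qualities visible in EvG-stained peripheral nerve —
#' organized nervous tissue (intact, round fascicles), unorganized nervous
#' tissue (neuroma: mini-fascicles and regenerating sprouts), connective
#' tissue, adipose tissue, and erythrocytes. The integer coding is fixed
#' package-wide and is the channel order of every probability map.
#'
#' @return Named integer vector mapping class name to mask value (0-5).
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  c(background          = 0L,
    organized_nervous   = 1L,
    unorganized_nervous = 2L,
    connective          = 3L,
    adipose             = 4L,
    erythrocyte         = 5L)
}

#' @rdname tissue_classes
#' @param include_background logical; drop `"background"` if `FALSE`.
#' @export
tissue_class_names <- function(include_background = TRUE) {
  nm <- names(tissue_classes())
  if (include_background) nm else nm[-1L]
}

#' Sentinel value for unlabeled pixels in training masks
#'
#' Pixels carrying this value lie in no annotated region of interest and are
#' excluded from classifier training. Distinct from background (class 0),
#' which is a real, trainable class.
#' @export
MASK_UNLABELED <- 255L

#' EvG-like rendering palette
#'
#' Base RGB color (0-255) per tissue class used by the synthetic renderer.
#' The palette approximates an Elastica van Gieson stain — collagen
#' pink-red, nervous tissue yellow-tan, erythrocytes saturated red, adipose
#' near-white vacuoles — but is an invention of this package: only class
#' separability matters for exercising the pipeline, not stain calibration.
#'
#' @return 6 x 3 integer matrix, rows named by class, columns R, G, B.
#' @export
evg_palette <- function() {
  pal <- rbind(
    background          = c(235, 237, 240),  # cool off-white slide glass
    organized_nervous   = c(214, 178, 118),  # yellow-tan fascicle interior
    unorganized_nervous = c(158, 126,  92),  # darker brown-tan mini-fascicles
    connective          = c(203,  94, 122),  # pink-red collagen matrix
    adipose             = c(247, 241, 222),  # warm white vacuole
    erythrocyte         = c(188,  32,  42)   # saturated red
  )
  colnames(pal) <- c("R", "G", "B")
  storage.mode(pal) <- "integer"
  pal
}

#' Render a label mask as an RGB image for inspection
#'
#' @param mask integer matrix with values in 0-5 (and optionally the
#'   unlabeled sentinel 255, drawn mid-grey).
#' @param palette 6 x 3 RGB matrix, default [evg_palette()].
#' @return H x W x 3 integer array in 0-255.
#' @export
mask_to_rgb <- function(mask, palette = evg_palette()) {
  stopifnot(is.matrix(mask))
  idx <- as.integer(mask) + 1L
  idx[as.integer(mask) == MASK_UNLABELED] <- NA_integer_
  out <- array(0L, c(nrow(mask), ncol(mask), 3L))
  for (ch in 1:3) {
    v <- palette[, ch][idx]
    v[is.na(v)] <- 128L
    out[, , ch] <- v
  }
  out
}

# internal: validate a label mask (values in 0..5 plus optional sentinel)
assert_label_mask <- function(mask, allow_unlabeled = FALSE, what = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop(what, " must be a numeric matrix", call. = FALSE)
  vals <- unique(as.vector(mask))
  ok <- vals %in% 0:5 | (allow_unlabeled & vals == MASK_UNLABELED)
  if (!all(ok))
    stop(what, " contains invalid class values: ",
         paste(utils::head(vals[!ok], 5), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
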