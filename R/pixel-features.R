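#' Pixel feature configuration
#'
#' Ilastik-style per-pixel features feeding the random forest: raw color
#' plus, at each Gaussian scale, smoothed color, gradient magnitude and
#' local variance. Scales are Gaussian sigmas in pixels and must be
#' strictly increasing.
#'
#' @param scales positive, strictly increasing numeric vector of sigmas.
#' @param kinds subset of `raw_color`, `gaussian_smooth`,
#'   `gradient_magnitude`, `local_variance`; `raw_color` contributes its 3
#'   channels once, the others 3 channels per scale.
#' @return object of class `nm_feature_config`.
#' @export
feature_config <- function(scales = c(1, 2, 4, 8),
                           kinds = c("raw_color", "gaussian_smooth",
                                     "gradient_magnitude", "local_variance")) {
  all_kinds <- c("raw_color", "gaussian_smooth", "gradient_magnitude",
                 "local_variance")
  kinds <- match.arg(kinds, all_kinds, several.ok = TRUE)
  if (length(kinds) < 1L) stop("at least one feature kind", call. = FALSE)
  scales <- as.numeric(scales)
  if (any(scales <= 0) || any(diff(scales) <= 0))
    stop("scales must be strictly positive and increasing", call. = FALSE)
  structure(list(scales = scales, kinds = kinds, color_space = "RGB"),
            class = "nm_feature_config")
}

#' @rdname feature_config
#' @param config an `nm_feature_config`.
#' @export
n_features <- function(config) {
  scale_kinds <- setdiff(config$kinds, "raw_color")
  3L * length(config$scales) * length(scale_kinds) +
    if ("raw_color" %in% config$kinds) 3L else 0L
}

#' @rdname feature_config
#' @export
feature_names <- function(config) {
  nm <- character(0)
  ch <- c("R", "G", "B")
  if ("raw_color" %in% config$kinds) nm <- paste0("raw_", ch)
  for (s in config$scales)
    for (k in setdiff(config$kinds, "raw_color"))
      nm <- c(nm, paste0(k, "_s", s, "_", ch))
  nm
}

# internal: mirror-pad a matrix by `pad` pixels on every side (reflection
# without edge repetition; pad is clipped to dim-1 so reflection is valid)
mirror_pad <- function(m, pad) {
  H <- nrow(m); W <- ncol(m)
  pr <- min(pad, H - 1L); pc <- min(pad, W - 1L)
  ridx <- c(rev(seq_len(pr) + 1L), 1:H, H - seq_len(pr))
  cidx <- c(rev(seq_len(pc) + 1L), 1:W, W - seq_len(pc))
  m[ridx, cidx, drop = FALSE]
}

# internal: Gaussian blur via EBImage, on a mirror-padded copy so the
# boundary handling is reflective regardless of the backend's convention.
# Accepts a matrix or an H x W x K stack (all frames blurred in one call).
gblur_reflect <- function(m, sigma) {
  dm <- dim(m)
  H <- dm[1]; W <- dm[2]
  pad <- as.integer(ceiling(4 * sigma))
  pr <- min(pad, H - 1L); pc <- min(pad, W - 1L)
  ridx <- c(rev(seq_len(pr) + 1L), 1:H, H - seq_len(pr))
  cidx <- c(rev(seq_len(pc) + 1L), 1:W, W - seq_len(pc))
  p <- if (length(dm) == 2L) m[ridx, cidx, drop = FALSE] else
    m[ridx, cidx, , drop = FALSE]
  g <- EBImage::gblur(p, sigma = sigma)
  if (length(dm) == 2L)
    g[(pr + 1L):(pr + H), (pc + 1L):(pc + W), drop = FALSE]
  else
    g[(pr + 1L):(pr + H), (pc + 1L):(pc + W), , drop = FALSE]
}

# internal: central-difference partial derivatives with reflective edges.
# Derivatives are taken on the raw channel and smoothed afterwards
# (differentiation and Gaussian smoothing commute), so a constant image
# yields exactly zero gradient.
central_diff <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up    <- m[c(1L, 1:(H - 1L)), , drop = FALSE]
  down  <- m[c(2:H, H), , drop = FALSE]
  left  <- m[, c(1L, 1:(W - 1L)), drop = FALSE]
  right <- m[, c(2:W, W), drop = FALSE]
  list(dr = (down - up) / 2, dc = (right - left) / 2)
}

#' Extract per-pixel features
#'
#' @param image `H x W x 3` numeric array in 0-255 (internally scaled to
#'   0-1).
#' @param config [feature_config()].
#' @return `H x W x F` numeric array; `dimnames` on the third margin give
#'   channel names. `F = 3 * |scales| * |scale kinds| + 3` when raw color
#'   is requested.
#' @export
extract_pixel_features <- function(image, config = feature_config()) {
  stopifnot(inherits(config, "nm_feature_config"),
            length(dim(image)) == 3L, dim(image)[3] == 3L)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (min(H, W) < 4 * max(config$scales))
    warning("image (", H, "x", W, ") is smaller than 4 x max scale (",
            4 * max(config$scales), " px); large-scale features will be ",
            "dominated by boundary reflection")
  img <- image / 255
  F <- n_features(config)
  out <- array(NA_real_, c(H, W, F),
               dimnames = list(NULL, NULL, feature_names(config)))
  k <- 0L
  if ("raw_color" %in% config$kinds) {
    out[, , 1:3] <- img
    k <- 3L
  }
  scale_kinds <- setdiff(config$kinds, "raw_color")
  if (length(scale_kinds)) {
    need_grad <- "gradient_magnitude" %in% scale_kinds
    if (need_grad) {
      dr <- array(NA_real_, dim(img)); dc <- array(NA_real_, dim(img))
      for (ch in 1:3) {
        d <- central_diff(img[, , ch])
        dr[, , ch] <- d$dr; dc[, , ch] <- d$dc
      }
      grad_zero <- all(dr == 0) && all(dc == 0)
    }
    for (s in config$scales) {
      smooth <- if (any(c("gaussian_smooth", "local_variance") %in%
                          scale_kinds)) gblur_reflect(img, s)
      for (kind in scale_kinds) {
        f <- switch(kind,
          gaussian_smooth = smooth,
          gradient_magnitude = {
            # derivatives of the raw channels smoothed afterwards
            # (the operations commute), so a constant image gives an
            # exactly zero gradient
            if (grad_zero) array(0, dim(img)) else
              sqrt(gblur_reflect(dr, s)^2 + gblur_reflect(dc, s)^2)
          },
          local_variance = {
            v <- gblur_reflect(img * img, s) - smooth^2
            v[v < 0] <- 0
            v
          })
        out[, , k + 1:3] <- f
        k <- k + 3L
      }
    }
  }
  out
}
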