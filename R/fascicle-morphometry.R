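#' Morphometry configuration
#'
#' Parameters of the roundness-based post-processing that separates intact
#' fascicles from neuroma tissue: components of nervous tissue whose
#' circularity reaches `roundness_threshold` are relabeled organized,
#' the rest unorganized; components below `min_component_px` are treated
#' as classifier speckle and reassigned to connective tissue. Set
#' `min_component_px = 0` to disable speckle suppression.
#'
#' @param roundness_threshold circularity cut in (0, 1), default 0.6.
#' @param min_component_px minimum component size in pixels, default 50.
#' @param connectivity 4 or 8 (default) for component formation.
#' @return object of class `nm_morph_config`.
#' @export
morphometry_config <- function(roundness_threshold = 0.6,
                               min_component_px = 50,
                               connectivity = 8) {
  if (!(roundness_threshold > 0 && roundness_threshold < 1))
    stop("roundness_threshold must lie in (0, 1)", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(roundness_threshold = roundness_threshold,
                 min_component_px = as.integer(min_component_px),
                 connectivity = as.integer(connectivity)),
            class = "nm_morph_config")
}

#' Label connected components
#'
#' 4-connected labeling via [EBImage::bwlabel()]; for 8-connectivity,
#' labels that touch diagonally are merged afterwards with a union-find
#' pass.
#'
#' @param binary logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background), compacted
#'   to 1..n.
#' @export
label_components <- function(binary, connectivity = 8) {
  m <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  n <- max(lab)
  if (connectivity == 8 && n > 1L) {
    H <- nrow(lab); W <- ncol(lab)
    # diagonal neighbor pairs with two distinct labels
    a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # NW-SE
    a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # NE-SW
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # compact labels to 1..n
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# internal: Moore-neighbor trace of the outer boundary of a component.
# `binary` is a logical matrix containing exactly one component (possibly
# with holes; only the outer contour is traced). Returns the cyclic chain
# code (1..8 = N, NE, E, SE, S, SW, W, NW) of the boundary walk, or
# integer(0) for a single-pixel component.
trace_outer_boundary <- function(binary) {
  drs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dcs <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  # pad so neighbor lookups never leave the matrix
  H <- nrow(binary); W <- ncol(binary)
  b <- matrix(FALSE, H + 2L, W + 2L)
  b[2:(H + 1L), 2:(W + 1L)] <- binary
  hit <- which(b, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  p0 <- as.integer(hit[1, ])           # topmost, then leftmost pixel
  b0 <- c(p0[1], p0[2] - 1L)           # backtrack = West neighbor (empty)
  # direction index lookup from a (dr, dc) offset in {-1,0,1}^2
  dir_of <- matrix(NA_integer_, 3L, 3L)
  for (d in 1:8) dir_of[drs[d] + 2L, dcs[d] + 2L] <- d
  # Walk until the tracer state (pixel, backtrack) repeats; the chain is
  # the moves inside that cycle. This terminates on shapes (e.g. 1-px-wide
  # bars) where the classic revisit-the-start criterion loops forever.
  chain <- integer(0)
  p <- p0; bk <- b0
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(p, bk, collapse = ","), 0L, envir = seen)
  max_steps <- 4L * (H + 2L) * (W + 2L) + 8L
  step <- 0L
  repeat {
    back_dir <- dir_of[bk[1] - p[1] + 2L, bk[2] - p[2] + 2L]
    found <- FALSE
    prev <- bk
    for (j in 1:8) {
      d <- (back_dir + j - 1L) %% 8L + 1L  # clockwise, just past backtrack
      q <- c(p[1] + drs[d], p[2] + dcs[d])
      if (b[q[1], q[2]]) {
        chain <- c(chain, d)
        bk <- prev                     # last empty neighbor examined
        p <- q
        found <- TRUE
        break
      }
      prev <- q
    }
    if (!found) return(integer(0))     # isolated single pixel
    step <- step + 1L
    key <- paste(p, bk, collapse = ",")
    t0 <- mget(key, envir = seen, ifnotfound = list(NULL))[[1]]
    if (!is.null(t0)) {
      chain <- chain[(t0 + 1L):step]
      break
    }
    assign(key, step, envir = seen)
    if (step > max_steps)
      stop("boundary trace failed to terminate", call. = FALSE)
  }
  chain
}

# internal: corner-corrected boundary length from a chain code, in pixels.
# Even (axis) and odd (diagonal) steps get the Vossepoel-Smeulders weights
# 0.980 and 1.406, corners (direction changes) the -0.091 correction, and
# pi is added for the half-pixel dilation separating the pixel-center
# contour from the pixel-boundary contour of the digitized set.
chain_perimeter <- function(chain) {
  if (length(chain) == 0L) return(pi)  # single pixel: disk of radius 1/2
  diagonal <- chain %% 2L == 0L
  corners <- sum(chain != c(chain[-1], chain[1]))
  0.980 * sum(!diagonal) + 1.406 * sum(diagonal) - 0.091 * corners + pi
}

#' Circularity of a connected pixel component
#'
#' Shape factor `C = 4 pi A / P^2`: 1 for a disk, decreasing with boundary
#' irregularity; implements fascicle "roundness". Area is the pixel count;
#' the perimeter of the outer contour is estimated from the Moore chain
#' code with corner-corrected step weights. The result is clamped to
#' `[0, 1]`; a single-pixel component is defined to have roundness 1.
#'
#' @param coords 2-column matrix of 1-based (row, col) pixel coordinates,
#'   or a logical matrix containing one component.
#' @return circularity in `[0, 1]`.
#' @export
component_roundness <- function(coords) {
  if (is.logical(coords) || (is.matrix(coords) && !ncol(coords) == 2L)) {
    binary <- coords != 0
    coords <- which(binary, arr.ind = TRUE)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("empty component", call. = FALSE)
  if (nrow(coords) == 1L) return(1)
  r0 <- min(coords[, 1]); c0 <- min(coords[, 2])
  binary <- matrix(FALSE, max(coords[, 1]) - r0 + 1L,
                   max(coords[, 2]) - c0 + 1L)
  binary[cbind(coords[, 1] - r0 + 1L, coords[, 2] - c0 + 1L)] <- TRUE
  P <- chain_perimeter(trace_outer_boundary(binary))
  C <- 4 * pi * nrow(coords) / P^2
  min(max(C, 0), 1)
}

#' Reclassify nervous-tissue components by roundness
#'
#' Connected components are formed over the union of pixels predicted as
#' organized or unorganized nervous tissue. Components smaller than
#' `min_component_px` are reassigned to connective tissue (speckle
#' suppression); every surviving component is relabeled wholesale —
#' circularity at or above the threshold makes it an organized fascicle,
#' below it unorganized neuroma tissue. Non-nervous classes pass through
#' unchanged, so the total non-background pixel count is conserved.
#'
#' @param mask integer label mask (values 0-5).
#' @param config [morphometry_config()].
#' @param mpp microns per pixel, used only to report component areas and
#'   perimeters in physical units (default 1).
#' @return list with `mask` (the refined label mask) and `components`
#'   (data.frame: component_id, pixel_count, area_um2, perimeter_um,
#'   roundness, assigned_class).
#' @export
reclassify_fascicles <- function(mask, config = morphometry_config(),
                                 mpp = 1) {
  assert_label_mask(mask)
  classes <- tissue_classes()
  nervous <- mask == classes[["organized_nervous"]] |
    mask == classes[["unorganized_nervous"]]
  comp_df <- data.frame(component_id = integer(0), pixel_count = integer(0),
                        area_um2 = numeric(0), perimeter_um = numeric(0),
                        roundness = numeric(0), assigned_class = character(0),
                        stringsAsFactors = FALSE)
  if (!any(nervous)) return(list(mask = mask, components = comp_df))
  lab <- label_components(nervous, config$connectivity)
  refined <- mask
  idx <- which(lab > 0L)
  comps <- split(idx, lab[idx])
  rows <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    px <- comps[[i]]
    coords <- cbind((px - 1L) %% nrow(mask) + 1L,
                    (px - 1L) %/% nrow(mask) + 1L)
    n_px <- length(px)
    if (n_px < config$min_component_px) {
      refined[px] <- classes[["connective"]]
      rows[[i]] <- NULL
      next
    }
    chain <- if (n_px == 1L) integer(0) else {
      r0 <- min(coords[, 1]); c0 <- min(coords[, 2])
      binary <- matrix(FALSE, max(coords[, 1]) - r0 + 1L,
                       max(coords[, 2]) - c0 + 1L)
      binary[cbind(coords[, 1] - r0 + 1L, coords[, 2] - c0 + 1L)] <- TRUE
      trace_outer_boundary(binary)
    }
    P <- chain_perimeter(chain)
    C <- if (n_px == 1L) 1 else min(max(4 * pi * n_px / P^2, 0), 1)
    cls <- if (C >= config$roundness_threshold) "organized_nervous" else
      "unorganized_nervous"
    refined[px] <- classes[[cls]]
    rows[[i]] <- data.frame(component_id = i, pixel_count = n_px,
                            area_um2 = n_px * mpp^2,
                            perimeter_um = P * mpp,
                            roundness = C, assigned_class = cls,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) comp_df <- do.call(rbind, rows)
  list(mask = refined, components = comp_df)
}

#' Normalized deviation index
#'
#' `(unorganized - organized) / max(unorganized, organized)`, computed on
#' areas (relative or absolute — the index is scale invariant). The index
#' lies in `[-1, 1]`: +1 means only unorganized nervous tissue is present,
#' -1 only organized (as in control nerves). When both areas are zero the
#' formula is 0/0 and the index is undefined; `NA` is returned and such
#' samples are excluded from downstream correlations.
#'
#' @param unorganized,organized nonnegative areas.
#' @return index in `[-1, 1]`, or `NA_real_` when both areas are zero.
#' @export
normalized_deviation_index <- function(unorganized, organized) {
  if (unorganized < 0 || organized < 0)
    stop("areas must be nonnegative", call. = FALSE)
  if (unorganized == 0 && organized == 0) return(NA_real_)
  (unorganized - organized) / max(unorganized, organized)
}

#' Quantify per-sample tissue composition
#'
#' Relative area per class = pixel count / total non-background pixels;
#' absolute area per class = pixel count x mpp^2 / 1e6, in mm^2.
#' Background is excluded from numerator and denominator. The denominator
#' of the relative areas includes erythrocytes by default (fractions of
#' total tissue area); set `include_erythrocytes = FALSE` to restrict the
#' denominator to the four structural classes.
#'
#' @param mask refined label mask.
#' @param mpp microns per pixel (> 0).
#' @param sample_id identifier echoed into the output row.
#' @param include_erythrocytes include class 5 in the relative-area
#'   denominator (default TRUE).
#' @return one-row data.frame: `sample_id`, `rel_<class>` and
#'   `abs_<class>_mm2` for the five tissue classes, `deviation_index`,
#'   `tissue_px`.
#' @export
quantify_composition <- function(mask, mpp, sample_id = NA_character_,
                                 include_erythrocytes = TRUE) {
  if (!is.numeric(mpp) || mpp <= 0) stop("mpp must be > 0", call. = FALSE)
  assert_label_mask(mask)
  classes <- tissue_classes()
  tissue <- names(classes)[-1]
  counts <- vapply(tissue, function(nm) sum(mask == classes[[nm]]),
                   numeric(1))
  total <- sum(counts)
  if (total == 0)
    stop("mask contains no non-background pixels", call. = FALSE)
  denom <- if (include_erythrocytes) total else
    sum(counts[setdiff(tissue, "erythrocyte")])
  rel <- counts / denom
  abs_mm2 <- counts * mpp^2 / 1e6
  out <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  for (nm in tissue) out[[paste0("rel_", nm)]] <- unname(rel[nm])
  for (nm in tissue) out[[paste0("abs_", nm, "_mm2")]] <- unname(abs_mm2[nm])
  out$deviation_index <- normalized_deviation_index(
    counts[["unorganized_nervous"]], counts[["organized_nervous"]])
  out$tissue_px <- total
  out
}

#' Composition table for a set of refined masks
#'
#' @param masks named list of refined label masks, names = sample ids.
#' @param records cohort data.frame supplying `mpp` per sample.
#' @param ... passed to [quantify_composition()].
#' @return data.frame with one row per sample.
#' @export
composition_table <- function(masks, records, ...) {
  stopifnot(!is.null(names(masks)))
  missing <- setdiff(names(masks), records$sample_id)
  if (length(missing))
    stop("no cohort record for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(rbind, lapply(names(masks), function(id) {
    mpp <- records$mpp[match(id, records$sample_id)]
    quantify_composition(masks[[id]], mpp = mpp, sample_id = id, ...)
  }))
}
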