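#' Train a random-forest pixel classifier
#'
#' Fits a probability forest on labeled pixels pooled from one or more
#' images. Labels come from training masks (class codes 0-5; pixels with
#' the sentinel 255 are unlabeled and ignored). Class imbalance is handled
#' by capping each class at `max_pixels_per_class` pixels, subsampled
#' deterministically: candidate pixels are ordered by (image name, row,
#' col) before the seeded draw, so the result does not depend on the order
#' in which images are supplied. A 10% stratified split is held out to
#' report pixel accuracy; classes with fewer than 10 labeled pixels stay
#' entirely in the training split.
#'
#' @param images list of `H x W x 3` arrays (0-255); names, if given, key
#'   the deterministic subsampling, otherwise `img_001`, ... are assigned.
#' @param masks list of matching label masks (values 0-5 and 255).
#' @param config [feature_config()].
#' @param n_trees number of trees (default 100).
#' @param seed integer seed controlling subsampling, the held-out split and
#'   forest growth.
#' @param max_pixels_per_class per-class pixel cap (default 50000).
#' @return object of class `nm_model`: the fitted forest, config and class
#'   map echoes, and a training summary (per-class pixel counts, held-out
#'   accuracy).
#' @export
train_classifier <- function(images, masks, config = feature_config(),
                             n_trees = 100, seed = 1,
                             max_pixels_per_class = 50000) {
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  if (is.null(names(images)))
    names(images) <- sprintf("img_%03d", seq_along(images))
  classes <- tissue_classes()

  # gather labeled pixels per image, in (name, row, col) order
  tabs <- list()
  for (nm in sort(names(images))) {
    img <- images[[nm]]
    mask <- masks[[match(nm, names(images))]]
    assert_label_mask(mask, allow_unlabeled = TRUE)
    stopifnot(dim(img)[1:2] == dim(mask))
    lab <- which(mask != MASK_UNLABELED, arr.ind = TRUE)
    if (nrow(lab) == 0L) next
    lab <- lab[order(lab[, 1], lab[, 2]), , drop = FALSE]
    feats <- extract_pixel_features(img, config)
    fm <- matrix(feats, nrow = prod(dim(mask)), ncol = dim(feats)[3])
    idx <- (lab[, 2] - 1L) * dim(mask)[1] + lab[, 1]
    tabs[[nm]] <- list(x = fm[idx, , drop = FALSE], y = mask[idx])
  }
  if (length(tabs) == 0L)
    stop("no labeled pixels: all training masks are entirely unlabeled ",
         "(sentinel 255)", call. = FALSE)
  x <- do.call(rbind, lapply(tabs, `[[`, "x"))
  y <- unlist(lapply(tabs, `[[`, "y"), use.names = FALSE)

  counts <- vapply(classes, function(k) sum(y == k), integer(1))
  if (any(counts == 0L))
    stop("class(es) with zero labeled pixels: ",
         paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)

  # deterministic per-class cap
  keep <- logical(length(y))
  for (k in classes) {
    idx <- which(y == k)
    if (length(idx) > max_pixels_per_class) {
      set.seed(seed + 13L * (k + 1L))
      idx <- idx[sort(sample.int(length(idx), max_pixels_per_class))]
    }
    keep[idx] <- TRUE
  }
  x <- x[keep, , drop = FALSE]
  y <- y[keep]

  # stratified 10% held-out split for the accuracy summary
  set.seed(seed + 101L)
  test_idx <- integer(0)
  for (k in classes) {
    idx <- which(y == k)
    if (length(idx) >= 10L)
      test_idx <- c(test_idx, idx[sort(sample.int(length(idx),
                                                  floor(0.1 * length(idx))))])
  }
  train_idx <- setdiff(seq_along(y), test_idx)

  df <- data.frame(.class = factor(y, levels = classes), x)
  colnames(df) <- c(".class", feature_names(config))
  forest <- ranger::ranger(
    dependent.variable.name = ".class",
    data = df[train_idx, , drop = FALSE],
    num.trees = n_trees, probability = TRUE,
    seed = seed, num.threads = 1L)

  held_out <- NA_real_
  per_class <- NULL
  if (length(test_idx)) {
    pr <- stats::predict(forest, df[test_idx, -1, drop = FALSE],
                         num.threads = 1L)$predictions
    pred <- as.integer(colnames(pr))[max.col(pr, ties.method = "first")]
    truth <- y[test_idx]
    held_out <- mean(pred == truth)
    per_class <- vapply(classes, function(k) {
      sel <- truth == k
      if (any(sel)) mean(pred[sel] == k) else NA_real_
    }, numeric(1))
  }

  structure(list(
    forest = forest,
    config = config,
    class_map = classes,
    n_trees = n_trees,
    seed = seed,
    summary = list(
      pixels_per_class = counts,
      pixels_used = vapply(classes, function(k) sum(y == k), integer(1)),
      held_out_accuracy = held_out,
      held_out_accuracy_per_class = per_class)
  ), class = "nm_model")
}

#' @export
print.nm_model <- function(x, ...) {
  cat("Random-forest pixel classifier (", x$n_trees, " trees, seed ",
      x$seed, ")\n", sep = "")
  cat("  features:", n_features(x$config), "channels\n")
  cat("  training pixels:",
      paste(names(x$summary$pixels_used), x$summary$pixels_used,
            sep = "=", collapse = ", "), "\n")
  cat("  held-out pixel accuracy:",
      format(x$summary$held_out_accuracy, digits = 4), "\n")
  invisible(x)
}

#' Save / load a trained classifier
#'
#' Serialization is faithful: a reloaded model produces bit-identical hard
#' labels.
#' @param model `nm_model`.
#' @param path `.rds` file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nm_model"))
    stop("file does not contain a neuromorph classifier: ", path,
         call. = FALSE)
  if (!identical(model$class_map, tissue_classes()))
    stop("model class map does not match the package class map",
         call. = FALSE)
  model
}

# internal: tile grid covering H x W with core tiles of side `tile` and
# `overlap` px of context on each side (clipped at the image border)
tile_grid <- function(H, W, tile, overlap) {
  starts <- function(n) if (n <= tile) 1L else seq(1L, n, by = tile)
  grid <- expand.grid(r0 = starts(H), c0 = starts(W))
  lapply(seq_len(nrow(grid)), function(i) {
    r0 <- grid$r0[i]; c0 <- grid$c0[i]
    r1 <- min(H, r0 + tile - 1L); c1 <- min(W, c0 + tile - 1L)
    list(core = c(r0, r1, c0, c1),
         ctx = c(max(1L, r0 - overlap), min(H, r1 + overlap),
                 max(1L, c0 - overlap), min(W, c1 + overlap)))
  })
}

#' Predict per-pixel class probabilities
#'
#' Produces the six-channel probability map: one channel per tissue class
#' in the fixed package order, per-pixel channel sums equal to 1. Large
#' images are processed in square tiles with overlapping context so memory
#' stays bounded; each pixel takes its prediction from the tile whose core
#' contains it.
#'
#' @param model `nm_model` from [train_classifier()].
#' @param image `H x W x 3` array in 0-255.
#' @param tile_size core tile side in px (default 1024).
#' @param overlap context margin in px (default 32).
#' @return `H x W x 6` numeric array, third margin named by class.
#' @export
predict_probability <- function(model, image, tile_size = 1024,
                                overlap = 32) {
  stopifnot(inherits(model, "nm_model"),
            length(dim(image)) == 3L, dim(image)[3] == 3L)
  H <- dim(image)[1]; W <- dim(image)[2]
  classes <- model$class_map
  out <- array(NA_real_, c(H, W, length(classes)),
               dimnames = list(NULL, NULL, names(classes)))
  expected_f <- length(model$forest$forest$independent.variable.names)
  for (t in tile_grid(H, W, as.integer(tile_size), as.integer(overlap))) {
    cx <- t$ctx
    sub <- image[cx[1]:cx[2], cx[3]:cx[4], , drop = FALSE]
    feats <- suppressWarnings(extract_pixel_features(sub, model$config))
    f <- dim(feats)[3]
    if (f != expected_f)
      stop("feature count mismatch: model expects ", expected_f,
           " channels, image yields ", f, call. = FALSE)
    fm <- matrix(feats, nrow = prod(dim(sub)[1:2]), ncol = f)
    colnames(fm) <- feature_names(model$config)
    pr <- stats::predict(model$forest, data.frame(fm),
                         num.threads = 1L)$predictions
    pr <- pr[, order(as.integer(colnames(pr))), drop = FALSE]
    arr <- array(pr, c(dim(sub)[1:2], length(classes)))
    co <- t$core
    rr <- (co[1]:co[2]) - cx[1] + 1L
    cc <- (co[3]:co[4]) - cx[3] + 1L
    out[co[1]:co[2], co[3]:co[4], ] <- arr[rr, cc, , drop = FALSE]
  }
  out
}

#' Harden a probability map into a label mask
#'
#' Per-pixel argmax over the six channels; ties break toward the lower
#' class index (so an all-uniform pixel becomes background).
#'
#' @param prob `H x W x 6` probability array.
#' @return integer label matrix with values 0-5.
#' @export
predict_labels <- function(prob) {
  stopifnot(length(dim(prob)) == 3L, dim(prob)[3] == 6L)
  H <- dim(prob)[1]; W <- dim(prob)[2]
  pm <- matrix(prob, nrow = H * W, ncol = 6L)
  lab <- max.col(pm, ties.method = "first") - 1L
  matrix(as.integer(lab), H, W)
}
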