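# Fixture constructors (all generated in code) and independent oracles.

# logical matrix with a centered rasterized disk of radius r
make_disk <- function(r, margin = 3) {
  n <- 2 * r + 2 * margin + 1
  cc <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
}

# logical matrix with a centered axis-aligned square of side s
make_square <- function(s, margin = 5) {
  n <- s + 2 * margin
  m <- matrix(FALSE, n, n)
  m[(margin + 1):(margin + s), (margin + 1):(margin + s)] <- TRUE
  m
}

# star-shaped blob with deep radial spikes (low circularity by design)
make_star <- function(R = 30, k = 10, amp = 0.55, margin = 8) {
  n <- 2 * R + 2 * margin + 1
  cc <- (n + 1) / 2
  th <- atan2(outer(1:n, 1:n, function(i, j) i - cc),
              outer(1:n, 1:n, function(i, j) j - cc))
  rad <- sqrt(outer(1:n, 1:n, function(i, j) (i - cc)^2) +
                outer(1:n, 1:n, function(i, j) (j - cc)^2))
  rad <= R * (1 + amp * cos(k * th)) / (1 + amp)
}

# independent point-in-polygon oracle: winding-angle accumulation,
# structurally different from the scanline fill under test
winding_inside <- function(r, c, polygon) {
  v <- sweep(polygon, 2, c(r, c))
  n <- nrow(v)
  ang <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[i %% n + 1, ]
    ang <- ang + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  abs(ang) > pi
}

# brute-force per-pixel composition counter (independent of the package's
# tabulation path)
brute_composition <- function(mask, mpp) {
  cls <- neuromorph::tissue_classes()
  counts <- sapply(names(cls)[-1], function(nm) {
    n <- 0
    for (i in seq_len(nrow(mask)))
      for (j in seq_len(ncol(mask)))
        if (mask[i, j] == cls[[nm]]) n <- n + 1
    n
  })
  list(rel = counts / sum(counts), abs_mm2 = counts * mpp^2 / 1e6)
}

# a small random label mask with all classes present
random_mask <- function(n = 32, seed = 1) {
  set.seed(seed)
  matrix(sample(0:5, n * n, replace = TRUE), n, n)
}

# quick two-color training fixture: red and blue squares plus one pixel
# of every remaining class so the classifier precondition holds
two_color_fixture <- function(n = 60) {
  img <- array(0L, c(n, n, 3))
  img[, 1:(n / 2), 1] <- 255L                    # left half red
  img[, (n / 2 + 1):n, 3] <- 255L                # right half blue
  mask <- matrix(neuromorph::MASK_UNLABELED, n, n)
  mask[5:(n - 5), 5:(n / 2 - 5)] <- 1L           # red block -> organized
  mask[5:(n - 5), (n / 2 + 5):(n - 5)] <- 2L     # blue block -> unorganized
  # single synthetic pixels for the remaining classes, distinct colors
  pix <- list(c(0L, 10L, 10L, 10L), c(3L, 200L, 90L, 120L),
              c(4L, 240L, 240L, 220L), c(5L, 190L, 30L, 40L))
  for (k in seq_along(pix)) {
    p <- pix[[k]]
    img[1, k, ] <- p[2:4]
    mask[1, k] <- p[1]
  }
  list(image = img, mask = mask)
}

# one shared small-canvas pipeline run, computed on first use
pipeline_256 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- neuromorph::run_pipeline(
        neuromorph::cohort_spec(image_size = 256), seed = 19)
    cache
  }
})
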