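#' Cohort specification for the synthetic generator
#'
#' Describes a cohort of nerve cross-sections to render: group sizes, the
#' pain scores of the painful-neuroma group, image geometry, and the
#' target fraction of nervous tissue that is organized (round fascicles)
#' per group. The defaults ([default_cohort_spec()]) emulate the clinical
#' cohort the package models: 12 samples — 4 control nerves, 3 non-painful
#' neuromas (NRS 0) and 5 painful neuromas with NRS scores 5, 6, 7, 8, 8
#' (median 7, range 5-8) — with the organized fraction decreasing from
#' controls through non-painful to painful neuromas, and within the
#' painful group decreasing with NRS.
#'
#' @param n_control,n_nonpainful,n_painful group sizes.
#' @param painful_nrs integer NRS scores (0-10), one per painful sample.
#' @param image_size square canvas side in pixels (>= 256 to render).
#' @param mpp microns per pixel of the rendered images.
#' @param organized_fraction_by_group list with entries `control`,
#'   `nonpainful_neuroma` (scalars) and `painful_neuroma` (length-2 vector:
#'   target at the lowest and at the highest painful NRS; intermediate
#'   scores interpolate linearly).
#' @param nervous_fraction fraction of the nerve interior occupied by
#'   nervous tissue (organized + unorganized).
#' @param noise_sd per-channel Gaussian pixel noise, on the 0-1 intensity
#'   scale.
#' @param fraction_jitter_sd sd of the per-sample jitter added to the
#'   group's organized-fraction target.
#' @param seed integer master seed for cohort generation.
#' @return object of class `nm_cohort_spec`.
#' @export
cohort_spec <- function(n_control = 4, n_nonpainful = 3, n_painful = 5,
                        painful_nrs = c(5, 6, 7, 8, 8),
                        image_size = 512, mpp = 2,
                        organized_fraction_by_group = list(
                          control = 0.9,
                          nonpainful_neuroma = 0.6,
                          painful_neuroma = c(0.30, 0.10)),
                        nervous_fraction = 0.35,
                        noise_sd = 8 / 255,
                        fraction_jitter_sd = 0.02,
                        seed = 1) {
  stopifnot(n_control >= 0, n_nonpainful >= 0, n_painful >= 0)
  painful_nrs <- as.integer(painful_nrs)
  if (length(painful_nrs) != n_painful)
    stop("painful_nrs must have length n_painful", call. = FALSE)
  if (length(painful_nrs) && (min(painful_nrs) < 0 || max(painful_nrs) > 10))
    stop("NRS scores must lie in 0-10", call. = FALSE)
  if (mpp <= 0) stop("mpp must be > 0", call. = FALSE)
  f <- organized_fraction_by_group
  stopifnot(all(c("control", "nonpainful_neuroma", "painful_neuroma")
                %in% names(f)),
            length(f$painful_neuroma) == 2L,
            all(unlist(f) >= 0 & unlist(f) <= 1))
  structure(list(
    n_control = as.integer(n_control),
    n_nonpainful = as.integer(n_nonpainful),
    n_painful = as.integer(n_painful),
    painful_nrs = painful_nrs,
    image_size = as.integer(image_size),
    mpp = mpp,
    organized_fraction_by_group = f,
    nervous_fraction = nervous_fraction,
    noise_sd = noise_sd,
    fraction_jitter_sd = fraction_jitter_sd,
    seed = as.integer(seed)
  ), class = "nm_cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_spec <- function() cohort_spec()

#' Cohort metadata records for a specification
#'
#' Builds the per-sample clinical table: id, group, NRS, age, sex, mpp.
#' NRS is 0 for controls and non-painful neuromas by definition. Ages and
#' sexes are fixed deterministic sets matching the emulated cohort's
#' printed group summaries (painful: median age 32, range 23-61, 4 male /
#' 1 female; non-painful: median 40, range 38-55, all male; control:
#' median 56, range 25-77, 2 male / 2 female) and carry no information
#' about pain beyond group membership.
#'
#' @param spec [cohort_spec()].
#' @return data.frame of cohort records.
#' @export
cohort_records <- function(spec) {
  stopifnot(inherits(spec, "nm_cohort_spec"))
  grp_ages <- list(
    control = c(25, 47, 65, 77),
    nonpainful_neuroma = c(38, 40, 55),
    painful_neuroma = c(23, 27, 32, 45, 61))
  grp_sex <- list(
    control = c("male", "male", "female", "female"),
    nonpainful_neuroma = c("male", "male", "male"),
    painful_neuroma = c("male", "male", "male", "male", "female"))
  n <- c(control = spec$n_control, nonpainful_neuroma = spec$n_nonpainful,
         painful_neuroma = spec$n_painful)
  rows <- list()
  for (g in names(n)) {
    if (n[[g]] == 0L) next
    ages <- grp_ages[[g]]
    ages <- if (n[[g]] == length(ages)) ages else
      round(seq(min(ages), max(ages), length.out = n[[g]]))
    rows[[g]] <- data.frame(
      group = g,
      nrs = if (g == "painful_neuroma") spec$painful_nrs else
        rep(0L, n[[g]]),
      age = ages,
      sex = rep_len(grp_sex[[g]], n[[g]]),
      mpp = spec$mpp,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- cbind(sample_id = sprintf("S%02d", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  validate_cohort_records(df)
}

#' Target organized fraction for a record
#'
#' The generator's effect encoding: the fraction of nervous-tissue pixels
#' drawn as organized fascicles, before per-sample jitter. Controls and
#' non-painful neuromas take their group values; painful neuromas
#' interpolate linearly in NRS between the spec's two painful endpoints
#' (lowest and highest painful score), so pain and fascicular
#' disorganization are monotonically coupled.
#'
#' @param spec [cohort_spec()].
#' @param record one-row data.frame (a row of [cohort_records()]).
#' @return target fraction in `[0, 1]`.
#' @export
target_organized_fraction <- function(spec, record) {
  f <- spec$organized_fraction_by_group
  g <- record$group
  if (g != "painful_neuroma") return(f[[g]])
  lo <- min(spec$painful_nrs); hi <- max(spec$painful_nrs)
  if (hi == lo) return(mean(f$painful_neuroma))
  w <- (record$nrs - lo) / (hi - lo)
  (1 - w) * f$painful_neuroma[1] + w * f$painful_neuroma[2]
}

#' Sample per-record organized fractions (the generator's fraction stage)
#'
#' Draws the jittered organized fraction for every record, exactly as the
#' renderer does, without rendering pixels. Used for fraction-level Monte
#' Carlo (e.g. null calibration of the pain correlation) where full image
#' synthesis is unnecessary.
#'
#' @param spec [cohort_spec()].
#' @param records from [cohort_records()].
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   stream (the right choice inside a Monte-Carlo loop: consecutive
#'   small integer seeds give correlated generator initializations,
#'   which would silently couple the replicates).
#' @return numeric vector of fractions, one per record.
#' @export
sample_organized_fractions <- function(spec, records,
                                       seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(nrow(records)), function(i) {
    base <- target_organized_fraction(spec, records[i, ])
    min(max(base + stats::rnorm(1, 0, spec$fraction_jitter_sd), 0.02), 0.98)
  }, numeric(1))
}

# internal: pixel set of a rotated ellipse; returns logical matrix S x S
ellipse_pixels <- function(S, cr, cc, a, b, theta) {
  r0 <- max(1L, floor(cr - a - b)); r1 <- min(S, ceiling(cr + a + b))
  c0 <- max(1L, floor(cc - a - b)); c1 <- min(S, ceiling(cc + a + b))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- r0:r1; cc2 <- c0:c1
  dr <- outer(rr - cr, rep(1, length(cc2)))
  dc <- outer(rep(1, length(rr)), cc2 - cc)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  list(rows = rr, cols = cc2, sel = sel)
}

# internal: pixel set of a star-shaped blob (radial cosine perturbation),
# guaranteed low circularity for spike amplitude >= ~0.45
star_pixels <- function(S, cr, cc, R, k, amp, phase) {
  ext <- R + 1
  r0 <- max(1L, floor(cr - ext)); r1 <- min(S, ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(S, ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- r0:r1; cc2 <- c0:c1
  dr <- outer(rr - cr, rep(1, length(cc2)))
  dc <- outer(rep(1, length(rr)), cc2 - cc)
  th <- atan2(dr, dc)
  rad <- sqrt(dr^2 + dc^2)
  sel <- rad <= R * (1 + amp * cos(k * th + phase)) / (1 + amp)
  list(rows = rr, cols = cc2, sel = sel)
}

# internal: linear indices (column-major) of a shape's pixels on an
# S x S canvas; painting through linear indices keeps the mask update
# in place instead of copying submatrices
shape_idx <- function(shape, S) {
  if (is.null(shape)) return(integer(0))
  w <- which(shape$sel)
  nr <- length(shape$rows)
  r <- shape$rows[(w - 1L) %% nr + 1L]
  cc <- shape$cols[(w - 1L) %/% nr + 1L]
  (cc - 1L) * S + r
}

# internal: 2-px (chebyshev) dilation of a logical matrix
dilate2 <- function(m) {
  EBImage::dilate(matrix(as.numeric(m), nrow(m), ncol(m)),
                  EBImage::makeBrush(5, shape = "box")) > 0
}

#' Render one synthetic nerve cross-section with ground truth
#'
#' Draws an EvG-like nerve cross-section on a square canvas: an elliptical
#' nerve (bulbous for neuromas) filled with connective-tissue matrix;
#' organized fascicles as well-separated high-circularity ellipses;
#' unorganized (neuroma) tissue as merging clusters of star-shaped blobs
#' with low circularity by construction; adipose tissue as round pale
#' vacuoles; erythrocytes as small saturated-red specks; off-white
#' background outside the nerve. The image is the class palette plus
#' band-limited texture, a low-frequency illumination gradient and i.i.d.
#' Gaussian pixel noise; the truth mask records the generating class of
#' every pixel. The number of organized versus unorganized nervous pixels
#' is controlled so the achieved organized fraction tracks the record's
#' target (within the jitter).
#'
#' @param spec [cohort_spec()] with `image_size >= 256`.
#' @param record one row of [cohort_records()].
#' @param rng_seed integer seed; the same (spec, record, seed) triple
#'   renders a bit-identical sample.
#' @return object of class `nm_sample`: list with `image` (`S x S x 3`
#'   integer), `truth_mask`, `record`, `rendered_fractions` (named fraction
#'   of non-background pixels per tissue class) and
#'   `target_organized_fraction` (the jittered target used).
#' @export
render_sample <- function(spec, record, rng_seed = spec$seed) {
  stopifnot(inherits(spec, "nm_cohort_spec"))
  if (spec$image_size < 256)
    stop("image_size must be >= 256 to render a cross-section",
         call. = FALSE)
  set.seed(rng_seed)
  S <- spec$image_size
  sc <- S / 512                       # shape sizes scale with the canvas
  classes <- tissue_classes()
  mask <- matrix(0L, S, S)

  # nerve outline: neuromas are bulbous, controls slimmer
  is_neuroma <- record$group != "control"
  a_frac <- if (is_neuroma) stats::runif(1, 0.43, 0.47) else
    stats::runif(1, 0.33, 0.37)
  a <- a_frac * S
  b <- a * stats::runif(1, 0.85, 1.0)
  theta <- stats::runif(1, 0, pi)
  ctr <- S / 2 + stats::runif(2, -0.02 * S, 0.02 * S)
  nerve <- ellipse_pixels(S, ctr[1], ctr[2], a, b, theta)
  nerve_idx <- shape_idx(nerve, S)
  mask[nerve_idx] <- classes[["connective"]]
  interior_px <- length(nerve_idx)
  if (interior_px < 0.2 * S^2)
    stop("cannot pack connective: nerve outline degenerate", call. = FALSE)

  # organized-fraction target with per-sample jitter
  f_org <- min(max(target_organized_fraction(spec, record) +
                     stats::rnorm(1, 0, spec$fraction_jitter_sd),
                   0.02), 0.98)
  budget <- spec$nervous_fraction * interior_px
  org_target <- f_org * budget

  # organized fascicles: rotated ellipses, axis ratio >= 0.78, kept >= 2 px
  # apart from everything so each is one high-circularity component
  org_px <- 0L
  attempts <- 0L
  free_idx <- nerve_idx
  while (org_px < org_target) {
    attempts <- attempts + 1L
    if (attempts > 6000L)
      stop("cannot pack organized_nervous fascicles into the canvas",
           call. = FALSE)
    remaining <- org_target - org_px
    rmax <- min(42, max(13, sqrt(remaining / pi) + 6))
    ra <- stats::runif(1, 10, rmax) * sc
    rb <- ra * stats::runif(1, 0.78, 0.95)
    th <- stats::runif(1, 0, pi)
    ci <- free_idx[sample.int(length(free_idx), 1L)]
    cr <- (ci - 1L) %% S + 1L; cc <- (ci - 1L) %/% S + 1L
    # inflated test ellipse must sit wholly in free connective tissue
    test <- ellipse_pixels(S, cr, cc, ra + 2, rb + 2, th)
    if (is.null(test)) next
    if (min(test$rows) == 1L || max(test$rows) == S ||
        min(test$cols) == 1L || max(test$cols) == S) next
    tidx <- shape_idx(test, S)
    if (any(mask[tidx] != classes[["connective"]])) next
    pidx <- shape_idx(ellipse_pixels(S, cr, cc, ra, rb, th), S)
    mask[pidx] <- classes[["organized_nervous"]]
    org_px <- org_px + length(pidx)
    free_idx <- free_idx[mask[free_idx] == classes[["connective"]]]
  }

  # unorganized tissue: star blobs clustered and free to merge, kept off
  # the fascicles so component identities survive
  unorg_target <- org_px * (1 - f_org) / f_org
  forb <- dilate2(mask == classes[["organized_nervous"]])
  allowed <- (mask == classes[["connective"]]) & !forb
  k_clusters <- max(1L, round(unorg_target / (2500 * sc^2)))
  free_idx <- which(allowed)
  if (length(free_idx) < 2 * unorg_target)
    stop("cannot pack unorganized_nervous tissue into the canvas",
         call. = FALSE)
  centers <- arrayInd(sample(free_idx, k_clusters), dim(mask))
  unorg_px <- 0L
  attempts <- 0L; stale <- 0L
  while (unorg_px < unorg_target) {
    attempts <- attempts + 1L
    if (attempts > 30000L || stale > 600L)
      stop("cannot pack unorganized_nervous tissue into the canvas",
           call. = FALSE)
    ce <- centers[sample.int(k_clusters, 1L), ]
    cr <- stats::rnorm(1, ce[1], 0.09 * S)
    cc <- stats::rnorm(1, ce[2], 0.09 * S)
    R <- stats::runif(1, 9, 15) * sc
    shape <- star_pixels(S, cr, cc, R,
                         k = sample(7:11, 1L), amp = stats::runif(1, 0.5, 0.6),
                         phase = stats::runif(1, 0, 2 * pi))
    idx <- shape_idx(shape, S)
    idx <- idx[allowed[idx] & mask[idx] == classes[["connective"]]]
    if (length(idx) < 25L) { stale <- stale + 1L; next }
    stale <- 0L
    mask[idx] <- classes[["unorganized_nervous"]]
    unorg_px <- unorg_px + length(idx)
  }

  # adipose vacuoles: round pale holes; absolute amount independent of
  # group (relative amount then falls with the bulbous neuroma area)
  forb_nerv <- dilate2(mask == classes[["organized_nervous"]] |
                         mask == classes[["unorganized_nervous"]])
  allowed <- (mask == classes[["connective"]]) & !forb_nerv
  adi_target <- 0.05 * S^2 * stats::runif(1, 0.85, 1.15)
  adi_px <- 0L; attempts <- 0L
  while (adi_px < adi_target && attempts < 4000L) {
    attempts <- attempts + 1L
    cr <- stats::runif(1, 1, S); cc <- stats::runif(1, 1, S)
    ra <- stats::runif(1, 6, 13) * sc
    shape <- ellipse_pixels(S, cr, cc, ra, ra * stats::runif(1, 0.85, 1),
                            stats::runif(1, 0, pi))
    idx <- shape_idx(shape, S)
    idx <- idx[allowed[idx] & mask[idx] == classes[["connective"]]]
    if (length(idx) < 0.5 * pi * ra^2) next
    mask[idx] <- classes[["adipose"]]
    adi_px <- adi_px + length(idx)
  }

  # erythrocyte specks scattered through the connective matrix
  allowed <- mask == classes[["connective"]]
  ery_target <- 0.004 * S^2
  ery_px <- 0L; attempts <- 0L
  while (ery_px < ery_target && attempts < 4000L) {
    attempts <- attempts + 1L
    cr <- stats::runif(1, 1, S); cc <- stats::runif(1, 1, S)
    ra <- stats::runif(1, 1.2, 3) * sc
    shape <- ellipse_pixels(S, cr, cc, ra, ra, 0)
    idx <- shape_idx(shape, S)
    idx <- idx[allowed[idx] & mask[idx] == classes[["connective"]]]
    if (length(idx) == 0L) next
    mask[idx] <- classes[["erythrocyte"]]
    ery_px <- ery_px + length(idx)
  }

  # compose the RGB image: palette + texture + illumination + noise
  pal <- evg_palette() / 255
  tex <- EBImage::gblur(matrix(stats::rnorm(S * S), S, S), sigma = 3)
  tex <- tex / stats::sd(tex) * (5 / 255)
  phi <- stats::runif(1, 0, 2 * pi)
  amp <- stats::runif(1, 6, 12) / 255
  ramp <- (outer(seq_len(S) - S / 2, rep(1, S)) * cos(phi) +
             outer(rep(1, S), seq_len(S) - S / 2) * sin(phi)) / S * amp
  img <- array(0, c(S, S, 3))
  idx <- as.integer(mask) + 1L
  for (ch in 1:3) {
    base <- matrix(pal[idx, ch], S, S)
    noisy <- base + tex + ramp + stats::rnorm(S * S, 0, spec$noise_sd)
    img[, , ch] <- pmin(pmax(noisy, 0), 1)
  }
  img <- round(img * 255)
  storage.mode(img) <- "integer"

  tissue <- names(classes)[-1]
  counts <- vapply(tissue, function(nm) sum(mask == classes[[nm]]),
                   numeric(1))
  structure(list(
    image = img,
    truth_mask = mask,
    record = record,
    rendered_fractions = counts / sum(counts),
    target_organized_fraction = f_org
  ), class = "nm_sample")
}

#' Generate a full synthetic cohort in memory
#'
#' @param spec [cohort_spec()].
#' @return list with `records` (data.frame) and `samples` (named list of
#'   `nm_sample`, one per record); per-sample render seeds are derived
#'   deterministically from `spec$seed`.
#' @export
generate_cohort_samples <- function(spec) {
  records <- cohort_records(spec)
  seeds <- sample_seeds(spec$seed, nrow(records))
  samples <- lapply(seq_len(nrow(records)), function(i)
    render_sample(spec, records[i, ], rng_seed = seeds[i]))
  names(samples) <- records$sample_id
  list(records = records, samples = samples, seeds = seeds)
}

# internal: per-sample render seeds, kept inside 32-bit integer range
sample_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 131 + seq_len(n) * 100003) %% 2147483647)
}

#' Generate a cohort on disk
#'
#' Writes, per sample, the RGB image (`<id>_image.png`) and ground-truth
#' mask (`<id>_mask.png`), plus `cohort.csv` (the metadata records) and
#' `manifest.json` (spec echo, per-sample seeds, palette, rendered
#' fractions). Re-running with the same spec reproduces every file
#' bit-identically.
#'
#' @param spec [cohort_spec()].
#' @param out_dir writable output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
generate_cohort <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  gen <- generate_cohort_samples(spec)
  utils::write.csv(gen$records, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  per_sample <- list()
  for (i in seq_len(nrow(gen$records))) {
    id <- gen$records$sample_id[i]
    s <- gen$samples[[id]]
    img_f <- file.path(out_dir, paste0(id, "_image.png"))
    msk_f <- file.path(out_dir, paste0(id, "_mask.png"))
    write_image(s$image, img_f)
    write_mask(s$truth_mask, msk_f)
    per_sample[[id]] <- list(
      seed = gen$seeds[i],
      image = basename(img_f), mask = basename(msk_f),
      rendered_fractions = as.list(s$rendered_fractions),
      target_organized_fraction = s$target_organized_fraction)
  }
  manifest <- list(spec = unclass(spec),
                   class_map = as.list(tissue_classes()),
                   palette = apply(evg_palette(), 1, function(r)
                     as.list(r), simplify = FALSE),
                   samples = per_sample)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
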