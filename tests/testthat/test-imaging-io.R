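test_that("RGB images round-trip losslessly through PNG and TIFF", {
  set.seed(42)
  img <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  for (ext in c(".png", ".tif")) {
    f <- tempfile(fileext = ext)
    write_image(img, f)
    back <- read_image(f)
    expect_identical(back, array(as.integer(img), dim(img)))
    unlink(f)
  }
})

test_that("grayscale input is promoted to RGB with a warning", {
  f <- tempfile(fileext = ".png")
  png::writePNG(matrix(runif(100), 10, 10), f)
  expect_warning(img <- read_image(f), "grayscale")
  expect_equal(dim(img), c(10, 10, 3))
  expect_identical(img[, , 1], img[, , 3])
  unlink(f)
})

test_that("16-bit TIFF input is rejected naming the expected depth", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(48), c(4, 4, 3)), f, bits.per.sample = 16L)
  expect_error(read_image(f), "8-bit")
  unlink(f)
})

test_that("label masks round-trip through indexed-value PNG exactly", {
  set.seed(7)
  mask <- matrix(sample(c(0:5, 255L), 400, replace = TRUE), 20, 20)
  f <- tempfile(fileext = ".png")
  write_mask(mask, f)
  expect_identical(read_mask(f), matrix(as.integer(mask), 20, 20))
  unlink(f)
})

test_that("a 10x10 square ROI labels exactly 100 pixels on a 20x20 canvas", {
  roi <- roi_annotation(rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0)),
                        "adipose", id = "sq")
  mask <- rois_to_mask(list(roi), c(20, 20))
  expect_equal(sum(mask == 4), 100)
  expect_equal(sum(mask == MASK_UNLABELED), 300)
})

test_that("polygon fill agrees with an independent winding-number oracle", {
  set.seed(11)
  for (rep in 1:5) {
    k <- sample(3:7, 1)
    poly <- cbind(runif(k, 1, 19), runif(k, 1, 19))
    mask <- rois_to_mask(list(roi_annotation(poly, "connective")), c(20, 20))
    for (r in 0:19) for (c in 0:19) {
      expect_equal(mask[r + 1, c + 1] == 3,
                   winding_inside(r, c, poly),
                   info = sprintf("rep %d pixel (%d,%d)", rep, r, c))
    }
  }
})

test_that("ROI edge cases: empty list, overlap tie-break, bounds check", {
  empty <- rois_to_mask(list(), c(8, 8))
  expect_true(all(empty == MASK_UNLABELED))
  sq <- function(r0, c0, s, lab, id)
    roi_annotation(rbind(c(r0, c0), c(r0, c0 + s), c(r0 + s, c0 + s),
                         c(r0 + s, c0)), lab, id)
  m <- rois_to_mask(list(sq(0, 0, 6, "adipose", "a"),
                         sq(3, 3, 6, "erythrocyte", "b")), c(12, 12))
  expect_equal(m[5, 5], 5)   # overlap carries the later label
  expect_equal(m[2, 2], 4)
  expect_error(rois_to_mask(list(sq(0, 0, 30, "adipose", "oob")), c(12, 12)),
               "oob")
})

test_that("rasterized polygon boundary stays within 1 px of its vertices", {
  poly <- rbind(c(3, 3), c(3, 15), c(15, 15), c(15, 3))
  mask <- rois_to_mask(list(roi_annotation(poly, "connective")), c(20, 20))
  filled <- which(mask == 3, arr.ind = TRUE) - 1   # to 0-based coords
  for (i in seq_len(nrow(poly))) {
    d <- sqrt((filled[, 1] - poly[i, 1])^2 + (filled[, 2] - poly[i, 2])^2)
    expect_lt(min(d), 1.5)
  }
})

test_that("cohort table validation normalizes case and rejects bad rows", {
  df <- data.frame(sample_id = c("A", "B"),
                   group = c("Control", "PAINFUL_NEUROMA"),
                   nrs = c(0, 7), age = c(50, 30),
                   sex = c("Female", "male"), mpp = c(2, 2))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  rec <- read_cohort_table(f)
  expect_equal(rec$group, c("control", "painful_neuroma"))
  expect_equal(rec$sex, c("female", "male"))

  df$nrs[2] <- 11
  write.csv(df, f, row.names = FALSE)
  expect_error(read_cohort_table(f), "0-10")

  df$nrs[2] <- 7; df$mpp[1] <- -1
  write.csv(df, f, row.names = FALSE)
  expect_error(read_cohort_table(f), "mpp")

  df$mpp[1] <- 2; df$nrs[1] <- 3   # control with nonzero NRS
  write.csv(df, f, row.names = FALSE)
  expect_error(read_cohort_table(f), "NRS 0")
  unlink(f)
})

test_that("the default synthetic cohort table has 5 samples with NRS >= 5", {
  rec <- cohort_records(default_cohort_spec())
  f <- tempfile(fileext = ".csv")
  write.csv(rec, f, row.names = FALSE)
  back <- read_cohort_table(f)
  expect_equal(nrow(back), 12)
  expect_equal(sum(back$nrs >= 5), 5)
  unlink(f)
})
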