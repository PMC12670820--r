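test_that("circularity matches analytic shape factors", {
  expect_gte(component_roundness(make_disk(100)), 0.95)
  expect_lt(abs(component_roundness(make_square(100)) - pi / 4), 0.05)
  bar <- matrix(FALSE, 5, 110); bar[3, 6:105] <- TRUE
  expect_lt(component_roundness(bar), 0.2)
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(component_roundness(one), 1)
  expect_error(component_roundness(matrix(FALSE, 3, 3)), "empty")
})

test_that("roundness separates rendered fascicle and blob shapes", {
  expect_gte(component_roundness(make_disk(25)), 0.7)
  expect_lte(component_roundness(make_star(R = 15, k = 8)), 0.5)
  expect_lte(component_roundness(make_star(R = 30, k = 10)), 0.5)
})

test_that("connected component labeling honors the connectivity choice", {
  m <- matrix(0L, 8, 8); m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
})

test_that("round components are rescued to organized and stars demoted", {
  cfg <- morphometry_config()
  disk <- make_disk(30)
  mask <- matrix(0L, nrow(disk), ncol(disk))
  mask[disk] <- 2L                       # disk mislabeled unorganized
  out <- reclassify_fascicles(mask, cfg)
  expect_true(all(out$mask[disk] == 1L))
  expect_equal(out$components$assigned_class, "organized_nervous")

  star <- make_star()
  mask2 <- matrix(0L, nrow(star), ncol(star))
  mask2[star] <- 1L                      # star mislabeled organized
  out2 <- reclassify_fascicles(mask2, cfg)
  expect_true(all(out2$mask[star] == 2L))
})

test_that("masks without nervous tissue pass through unchanged", {
  mask <- matrix(c(0L, 3L, 4L, 5L), 10, 10)
  out <- reclassify_fascicles(mask)
  expect_identical(out$mask, mask)
  expect_equal(nrow(out$components), 0)
})

test_that("speckle components move to connective, conserving tissue count", {
  mask <- matrix(0L, 50, 50)
  mask[5:8, 5:8] <- 2L                   # 16 px speck, below threshold
  disk <- make_disk(10)
  mask[15:(14 + nrow(disk)), 15:(14 + ncol(disk))][disk] <- 2L
  out <- reclassify_fascicles(mask, morphometry_config(min_component_px = 50))
  expect_true(all(out$mask[5:8, 5:8] == 3L))
  expect_equal(sum(out$mask != 0), sum(mask != 0))      # conservation
  expect_equal(sum(out$mask %in% 1:2), sum(mask %in% 1:2) - 16)
  out0 <- reclassify_fascicles(mask, morphometry_config(min_component_px = 0))
  expect_equal(sum(out0$mask %in% 1:2), sum(mask %in% 1:2))
})

test_that("deviation index reproduces its defining extremes and identities", {
  expect_equal(normalized_deviation_index(0.5, 0), 1)
  expect_equal(normalized_deviation_index(0, 0.5), -1)
  expect_equal(normalized_deviation_index(0.3, 0.3), 0)
  expect_equal(normalized_deviation_index(0.6, 0.2), (0.6 - 0.2) / 0.6)
  expect_true(is.na(normalized_deviation_index(0, 0)))
  expect_error(normalized_deviation_index(-1, 0.5), "nonnegative")
  set.seed(3)
  for (i in 1:50) {                      # scale invariance + antisymmetry
    u <- runif(1); o <- runif(1); k <- runif(1, 0.01, 100)
    expect_equal(normalized_deviation_index(k * u, k * o),
                 normalized_deviation_index(u, o))
    expect_equal(normalized_deviation_index(u, o),
                 -normalized_deviation_index(o, u))
    expect_lte(abs(normalized_deviation_index(u, o)), 1)
  }
})

test_that("composition quantifier matches worked examples and brute force", {
  mask <- matrix(0L, 10, 10)
  mask[1:4, ] <- 1L; mask[5:8, ] <- 2L   # 40 px each, 20 background
  comp <- quantify_composition(mask, mpp = 1, sample_id = "x")
  expect_equal(comp$rel_organized_nervous, 0.5)
  expect_equal(comp$rel_unorganized_nervous, 0.5)
  expect_equal(comp$abs_organized_nervous_mm2, 4e-5)
  expect_equal(comp$deviation_index, 0)

  adi <- matrix(4L, 6, 6)
  ca <- quantify_composition(adi, mpp = 2)
  expect_equal(ca$rel_adipose, 1)
  expect_equal(ca$rel_connective, 0)

  expect_error(quantify_composition(matrix(0L, 4, 4), mpp = 1),
               "non-background")
  expect_error(quantify_composition(adi, mpp = 0), "mpp")

  for (seed in 1:5) {                    # brute-force agreement
    m <- random_mask(32, seed)
    comp <- quantify_composition(m, mpp = 1.7)
    oracle <- brute_composition(m, mpp = 1.7)
    for (nm in names(oracle$rel)) {
      expect_equal(comp[[paste0("rel_", nm)]], unname(oracle$rel[nm]))
      expect_equal(comp[[paste0("abs_", nm, "_mm2")]],
                   unname(oracle$abs_mm2[nm]))
    }
  }
})

test_that("erythrocytes can be excluded from the relative denominator", {
  mask <- matrix(0L, 10, 10)
  mask[1:5, ] <- 1L; mask[6:8, ] <- 5L
  with_e <- quantify_composition(mask, mpp = 1)
  without_e <- quantify_composition(mask, mpp = 1,
                                    include_erythrocytes = FALSE)
  expect_equal(with_e$rel_organized_nervous, 50 / 80)
  expect_equal(without_e$rel_organized_nervous, 1)
})
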