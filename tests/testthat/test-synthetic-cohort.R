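test_that("the default cohort matches the emulated clinical structure", {
  spec <- default_cohort_spec()
  rec <- cohort_records(spec)
  expect_equal(nrow(rec), 12)
  expect_equal(spec$n_nonpainful, 3L)
  pain <- rec$nrs[rec$group == "painful_neuroma"]
  expect_equal(length(pain), 5)
  expect_equal(median(pain), 7)
  expect_equal(min(pain), 5)
  expect_equal(max(pain), 8)
  expect_true(all(rec$nrs[rec$group != "painful_neuroma"] == 0))
})

test_that("cohort spec invariants are enforced", {
  expect_error(cohort_spec(n_painful = 2, painful_nrs = c(5, 6, 7)),
               "length")
  expect_error(cohort_spec(painful_nrs = c(5, 6, 7, 8, 11)), "0-10")
  expect_error(cohort_spec(mpp = 0), "mpp")
  expect_error(render_sample(cohort_spec(image_size = 128),
                             cohort_records(default_cohort_spec())[1, ]),
               "image_size")
})

test_that("rendering is a pure function of spec, record and seed", {
  spec <- cohort_spec(image_size = 256)
  rec <- cohort_records(spec)
  a <- render_sample(spec, rec[8, ], rng_seed = 77)
  b <- render_sample(spec, rec[8, ], rng_seed = 77)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_mask, b$truth_mask)
  c <- render_sample(spec, rec[8, ], rng_seed = 78)
  expect_false(identical(a$image, c$image))
})

test_that("rendered samples honor the ground-truth contracts", {
  spec <- cohort_spec(image_size = 256)
  rec <- cohort_records(spec)
  ids <- c(1, 5, 8, 12)    # one control, one non-painful, two painful
  for (i in ids) {
    s <- render_sample(spec, rec[i, ], rng_seed = 200 + i)
    expect_equal(dim(s$image)[1:2], dim(s$truth_mask))
    expect_equal(sum(s$rendered_fractions), 1, tolerance = 1e-9)
    achieved <- s$rendered_fractions[["organized_nervous"]] /
      (s$rendered_fractions[["organized_nervous"]] +
         s$rendered_fractions[["unorganized_nervous"]])
    expect_lt(abs(achieved - target_organized_fraction(spec, rec[i, ])), 0.1)
  }
})

test_that("controls carry almost no unorganized tissue; pain lowers the organized fraction", {
  spec <- cohort_spec(image_size = 256)
  rec <- cohort_records(spec)
  ctrl <- render_sample(spec, rec[1, ], rng_seed = 301)
  expect_lte(ctrl$rendered_fractions[["unorganized_nervous"]], 0.05)
  nonp <- render_sample(spec, rec[5, ], rng_seed = 302)
  painful <- render_sample(spec, rec[12, ], rng_seed = 303)  # NRS 8
  org_of_nervous <- function(s)
    s$rendered_fractions[["organized_nervous"]] /
      (s$rendered_fractions[["organized_nervous"]] +
         s$rendered_fractions[["unorganized_nervous"]])
  expect_lt(org_of_nervous(painful), org_of_nervous(nonp))
})

test_that("rendered shapes separate cleanly at the roundness threshold", {
  spec <- cohort_spec(image_size = 256)
  rec <- cohort_records(spec)
  s <- render_sample(spec, rec[9, ], rng_seed = 41)   # painful: both classes
  for (cls in 1:2) {
    lab <- label_components(s$truth_mask == cls, 8)
    idx <- which(lab > 0)
    comps <- split(idx, lab[idx])
    comps <- comps[lengths(comps) >= 50]
    rd <- sapply(comps, function(px) {
      component_roundness(cbind((px - 1) %% 256 + 1, (px - 1) %/% 256 + 1))
    })
    if (cls == 1) expect_true(all(rd >= 0.7)) else
      expect_true(all(rd <= 0.5))
  }
})

test_that("truth-mask organized fraction anticorrelates with NRS across the cohort", {
  spec <- cohort_spec(image_size = 256, seed = 5)
  gen <- generate_cohort_samples(spec)
  org <- sapply(gen$samples, function(s)
    s$rendered_fractions[["organized_nervous"]])
  rho <- cor(org, gen$records$nrs, method = "spearman")
  expect_lt(rho, 0)
})

test_that("on-disk generation writes a complete, reproducible cohort", {
  spec <- cohort_spec(image_size = 256, seed = 9)
  d1 <- file.path(tempdir(), "cohort_a")
  m1 <- generate_cohort(spec, d1)
  expect_length(list.files(d1, pattern = "_image\\.png$"), 12)
  expect_length(list.files(d1, pattern = "_mask\\.png$"), 12)
  rec <- read_cohort_table(file.path(d1, "cohort.csv"))
  expect_equal(nrow(rec), 12)

  # manifest fractions equal fractions recomputed from the mask files
  for (id in c("S01", "S10")) {
    mask <- read_mask(file.path(d1, paste0(id, "_mask.png")))
    counts <- sapply(tissue_class_names(FALSE), function(nm)
      sum(mask == tissue_classes()[[nm]]))
    expect_equal(unlist(m1$samples[[id]]$rendered_fractions),
                 counts / sum(counts), tolerance = 1e-9)
  }

  d2 <- file.path(tempdir(), "cohort_b")
  generate_cohort(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a painless spec yields a table with no positive NRS", {
  spec <- cohort_spec(n_painful = 0, painful_nrs = integer(0))
  rec <- cohort_records(spec)
  expect_equal(sum(rec$nrs > 0), 0)
  expect_equal(nrow(rec), 7)
})
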