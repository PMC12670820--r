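# independent oracle: two-sided exact Mann-Whitney p by enumerating every
# assignment of the pooled values to groups and counting, pair by pair,
# how many a-values exceed b-values
brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  ustat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- ustat(a, b)
  mid <- na * (n - na) / 2
  combs <- combn(n, na)
  us <- apply(combs, 2, function(idx)
    ustat(pooled[idx], pooled[-idx]))
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

make_fake_compositions <- function(records, seed = 1) {
  set.seed(seed)
  base_org <- ifelse(records$group == "control", 0.32,
                     ifelse(records$group == "nonpainful_neuroma", 0.21,
                            0.25 - 0.02 * records$nrs))
  org <- pmax(base_org + rnorm(nrow(records), 0, 0.005), 0.01)
  unorg <- ifelse(records$group == "control", 0.01, 0.30 - base_org)
  conn <- 0.5
  adi <- pmax(1 - org - unorg - conn - 0.01, 0.02)
  total_px <- 150000
  df <- data.frame(sample_id = records$sample_id,
                   rel_organized_nervous = org,
                   rel_unorganized_nervous = unorg,
                   rel_connective = conn, rel_adipose = adi,
                   rel_erythrocyte = 0.01)
  for (nm in c("organized_nervous", "unorganized_nervous", "connective",
               "adipose", "erythrocyte"))
    df[[paste0("abs_", nm, "_mm2")]] <-
      df[[paste0("rel_", nm)]] * total_px * records$mpp^2 / 1e6
  df$deviation_index <- mapply(normalized_deviation_index,
                               df$rel_unorganized_nervous,
                               df$rel_organized_nervous)
  df$tissue_px <- total_px
  df
}

test_that("the Lilliefors gate accepts normal draws at its nominal level", {
  flagged <- sapply(1:200, function(s) {
    set.seed(s)
    test_normality(rnorm(500))$normal
  })
  expect_gte(mean(flagged), 0.94)
})

test_that("the normality gate rejects two-point data and degenerate input", {
  set.seed(4)
  x <- sample(c(0, 1), 500, replace = TRUE)
  expect_false(test_normality(x)$normal)
  expect_error(test_normality(rep(2, 10)), "zero variance")
  expect_error(test_normality(rnorm(3)), "n >= 4")
})

test_that("Mann-Whitney exact p matches brute-force enumeration", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6), force_nonparametric = TRUE)
  expect_equal(r$test_name, "mann_whitney_u")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(brute_mw_p(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(17)
  for (i in 1:8) {                        # random small samples, with ties
    a <- sample(1:6, sample(3:5, 1), replace = TRUE)
    b <- sample(1:6, sample(3:5, 1), replace = TRUE)
    r <- compare_groups(a, b, force_nonparametric = TRUE)
    expect_equal(r$p_value, brute_mw_p(a, b), info = paste("case", i))
  }
})

test_that("tie-free exact p agrees with the base wilcox.test reference", {
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(6)
    r <- compare_groups(a, b, force_nonparametric = TRUE)
    w <- wilcox.test(a, b, exact = TRUE)
    expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give p ~ 1 and exact matches the approximation", {
  r <- compare_groups(c(1, 2, 3), c(1, 2, 3), force_nonparametric = TRUE)
  expect_gte(r$p_value, 0.99)

  set.seed(31)
  for (i in 1:10) {                       # tie-free pooled n = 12
    a <- rnorm(6); b <- rnorm(6, 0.5)
    pe <- neuromorph:::mann_whitney_u(a, b, exact_max_n = 12L)
    pa <- neuromorph:::mann_whitney_u(a, b, exact_max_n = 0L)
    expect_equal(pe$method, "exact")
    expect_equal(pa$method, "normal_approx")
    expect_lte(abs(pe$p - pa$p), 0.05)
  }
})

test_that("degenerate and small groups are auto-routed to Mann-Whitney", {
  ctrl <- c(0, 0, 0, 0)                   # constant: unorganized in controls
  neur <- c(0.2, 0.3, 0.25, 0.31, 0.28, 0.22, 0.35, 0.27)
  r <- compare_groups(ctrl, neur)
  expect_equal(r$test_name, "mann_whitney_u")
  small <- c(1.2, 1.4, 1.3)               # n = 3: normality unverifiable
  r2 <- compare_groups(small, neur)
  expect_equal(r2$test_name, "mann_whitney_u")
  expect_error(compare_groups(c(1), c(2, 3)), "n >= 2")
})

test_that("normal-looking groups take the t-test branch, matching t.test", {
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30, 0.8)
  r <- compare_groups(a, b)
  expect_equal(r$test_name, "t_independent")
  expect_equal(r$p_value, t.test(a, b, var.equal = TRUE)$p.value)
  rw <- compare_groups(a, b, welch = TRUE)
  expect_equal(rw$p_value, t.test(a, b)$p.value)
})

test_that("Spearman rho reproduces exact ranks, ties and the t approximation", {
  expect_equal(spearman_correlation(1:4, 4:1)$statistic, -1)
  expect_equal(spearman_correlation(1:4, 1:4)$statistic, 1)

  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  # hand-expanded mid-rank Pearson oracle
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  r <- spearman_correlation(x, y)
  expect_equal(r$statistic, num / den)

  set.seed(8)
  x2 <- rnorm(20); y2 <- x2 + rnorm(20)
  ct <- suppressWarnings(cor.test(x2, y2, method = "spearman",
                                  exact = FALSE))
  r2 <- spearman_correlation(x2, y2)
  expect_equal(r2$statistic, unname(ct$estimate))
  expect_equal(r2$p_value, ct$p.value, tolerance = 1e-12)

  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 3:1), "n >= 4")

  rp <- spearman_correlation(x2, y2, n_perm = 500, seed = 2)
  expect_true(rp$p_permutation > 0 && rp$p_permutation <= 1)
})

test_that("the full report covers every comparison of the analysis design", {
  rec <- cohort_records(default_cohort_spec())
  comp <- make_fake_compositions(rec)
  rep <- run_full_analysis(comp, rec, bh_adjust = TRUE)
  res <- rep$results
  expect_equal(sum(res$comparison == "control_vs_neuroma", na.rm = TRUE), 8)
  expect_equal(sum(res$comparison == "painful_vs_nonpainful", na.rm = TRUE), 8)
  expect_true(all(c("nrs_rel_unorganized", "nrs_rel_organized",
                    "nrs_deviation_index", "nrs_age", "nrs_sex")
                  %in% res$analysis))
  expect_true("p_bh" %in% names(res))
  ok <- !is.na(res$p_value)
  expect_true(all(res$p_value[ok] >= 0 & res$p_value[ok] <= 1))
  # encoded effects point the right way
  expect_lt(res$statistic[res$analysis == "nrs_rel_organized"], 0)
  expect_gt(res$statistic[res$analysis == "nrs_deviation_index"], 0)
})

test_that("constant NRS flags correlation rows instead of failing", {
  spec <- cohort_spec(painful_nrs = c(0, 0, 0, 0, 0))
  rec <- cohort_records(spec)
  comp <- make_fake_compositions(rec)
  rep <- run_full_analysis(comp, rec)
  row <- rep$results[rep$results$analysis == "nrs_rel_organized", ]
  expect_true(grepl("not computable", row$note))
  expect_true(is.na(row$p_value))
})

test_that("a missing composition is reported by sample id", {
  rec <- cohort_records(default_cohort_spec())
  comp <- make_fake_compositions(rec)
  expect_error(run_full_analysis(comp[-3, ], rec), rec$sample_id[3])
})

test_that("significance annotation follows the figure convention", {
  expect_equal(annotate_significance(c(0.006, 0.03, 0.2, NA)),
               c("**", "*", "", ""))
})

test_that("effect-encoded cohorts recover the negative pain correlation", {
  spec <- default_cohort_spec()
  rec <- cohort_records(spec)
  neuroma <- rec$group != "control"
  set.seed(29)     # one stream for all replicates
  hits <- replicate(100, {
    f <- sample_organized_fractions(spec, rec, seed = NULL)
    cor(f[neuroma], rec$nrs[neuroma], method = "spearman") < 0
  })
  expect_gte(mean(hits), 0.95)
})
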