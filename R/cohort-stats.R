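# Statistical stage: normality-gated group comparisons and Spearman pain
# correlations over per-sample tissue compositions.

# internal: constructor for one result row
stat_row <- function(variable, comparison, test_name, statistic, p_value,
                     n_a, n_b = NA_integer_, effect_direction = NA_character_,
                     note = NA_character_) {
  data.frame(variable = variable, comparison = comparison,
             test_name = test_name, statistic = statistic,
             p_value = p_value, n_a = n_a, n_b = n_b,
             effect_direction = effect_direction, note = note,
             stringsAsFactors = FALSE)
}

# internal: Lilliefors KS statistic (estimated mean and SD)
lillie_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(pmax(seq_len(n) / n - z, z - (seq_len(n) - 1L) / n))
}

#' Lilliefors-type normality test
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal distribution
#' with mean and SD estimated from the sample, with the Lilliefors p-value
#' approximation (via [nortest::lillie.test()]). For n = 4 — below that
#' implementation's range — the p-value is computed by a seeded
#' Monte-Carlo null simulation of the same statistic (the statistic is
#' location-scale invariant, so standard-normal draws suffice). The
#' sample is flagged normal when p > 0.05.
#'
#' @param values numeric vector, n >= 4, non-constant.
#' @param variable label echoed into the result.
#' @return one-row data.frame (`test_name = "ks_normality"`) with the KS
#'   statistic, p-value and a logical `normal` column.
#' @export
test_normality <- function(values, variable = NA_character_) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4L)
    stop("normality test needs n >= 4", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate: zero variance", call. = FALSE)
  if (n >= 5L) {
    lt <- nortest::lillie.test(values)
    D <- unname(lt$statistic); p <- lt$p.value
  } else {
    D <- lillie_stat(values)
    seed_keep <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    set.seed(20071L)
    sims <- replicate(4999, lillie_stat(stats::rnorm(n)))
    if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, .GlobalEnv)
    p <- (1 + sum(sims >= D - 1e-12)) / 5000
  }
  out <- stat_row(variable, "normality", "ks_normality", D, p, n)
  out$normal <- out$p_value > 0.05
  out
}

# internal: Mann-Whitney U with mid-ranks; exact two-sided p by complete
# enumeration of group assignments when the pooled size allows it (the
# null distribution of U is symmetric about n_a*n_b/2 even under ties),
# otherwise the tie-corrected normal approximation with continuity
# correction.
mann_whitney_u <- function(a, b, exact_max_n = 12L) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mid <- n_a * n_b / 2
  if (n_a + n_b <= exact_max_n) {
    combs <- utils::combn(n_a + n_b, n_a)
    Us <- apply(combs, 2, function(idx)
      sum(rk[idx]) - n_a * (n_a + 1) / 2)
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    n <- n_a + n_b
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mid) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }
  list(U = U, p = p, method = method)
}

#' Compare two groups, choosing the test by normality
#'
#' Implements the selection rule of the analysis stage: a two-sided
#' Student's t-test for independent samples when both groups look normal,
#' and a two-sided Mann-Whitney U test otherwise. A group is routed to the
#' nonparametric branch when it is degenerate (constant — e.g. the
#' unorganized-tissue areas of control nerves, which are essentially all
#' zero), too small for the normality test (n < 4), or fails the
#' Lilliefors check at the 0.05 level. `force_nonparametric` bypasses the
#' gate. The Mann-Whitney p-value is computed by exact enumeration (with
#' ties) when the pooled sample size is at most 12, matching the cohort
#' scale, and by tie-corrected normal approximation above that.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param force_nonparametric always use Mann-Whitney.
#' @param welch use the Welch (unequal-variance) t-test instead of
#'   Student's when the parametric branch is taken.
#' @param variable,comparison labels echoed into the result.
#' @return one-row data.frame with `test_name` `"t_independent"` or
#'   `"mann_whitney_u"`.
#' @export
compare_groups <- function(a, b, force_nonparametric = FALSE,
                           welch = FALSE, variable = NA_character_,
                           comparison = NA_character_) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  looks_normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)      # degenerate
    if (length(x) < 4L) return(FALSE)         # cannot verify normality
    test_normality(x)$normal
  }
  nonpar <- force_nonparametric || !looks_normal(a) || !looks_normal(b)
  dir <- if (stats::median(a) > stats::median(b)) "a>b" else
    if (stats::median(a) < stats::median(b)) "a<b" else "a=b"
  if (nonpar) {
    mw <- mann_whitney_u(a, b)
    out <- stat_row(variable, comparison, "mann_whitney_u", mw$U, mw$p,
                    length(a), length(b), dir,
                    note = paste0("p_method=", mw$method))
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    out <- stat_row(variable, comparison, "t_independent",
                    unname(tt$statistic), tt$p.value,
                    length(a), length(b), dir,
                    note = if (welch) "welch" else "student")
  }
  out
}

#' Spearman rank correlation with tie correction
#'
#' Tie-corrected Spearman rho computed as the Pearson correlation of
#' mid-ranks; the two-sided p-value uses the t approximation with n - 2
#' degrees of freedom. Optionally a seeded Monte-Carlo permutation
#' p-value is computed as well.
#'
#' @param x,y numeric vectors of equal length, n >= 4, non-constant.
#' @param n_perm number of permutations for the optional Monte-Carlo
#'   p-value (0 = skip).
#' @param seed seed for the permutation draw.
#' @param variable,comparison labels echoed into the result.
#' @return one-row data.frame (`test_name = "spearman"`) with `statistic`
#'   = rho; the permutation p, when requested, lands in `p_permutation`.
#' @export
spearman_correlation <- function(x, y, n_perm = 0, seed = 1,
                                 variable = NA_character_,
                                 comparison = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("Spearman correlation needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate: constant input", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- stat_row(variable, comparison, "spearman", rho, p, n,
                  effect_direction = if (rho > 0) "positive" else
                    if (rho < 0) "negative" else "none")
  if (n_perm > 0) {
    set.seed(seed)
    perm <- replicate(n_perm, stats::cor(rx, sample(ry)))
    out$p_permutation <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) /
      (n_perm + 1)
  }
  out
}

#' Significance annotation in the figure convention
#'
#' One asterisk for p < 0.05, two for p < 0.01, empty string otherwise.
#' @param p p-value (vectorized).
#' @return character vector of annotations.
#' @export
annotate_significance <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# internal: a comparison row that survives non-computable inputs
safe_stat <- function(expr) {
  tryCatch(expr, error = function(e) {
    out <- stat_row(NA_character_, NA_character_, NA_character_,
                    NA_real_, NA_real_, NA_integer_)
    out$note <- paste0("not computable: ", conditionMessage(e))
    out
  })
}

#' Run the full statistical analysis of a cohort
#'
#' Reproduces the analysis stage over a per-sample composition table:
#' \itemize{
#' \item control vs pooled neuromas — relative and absolute areas of
#'   unorganized, organized, connective and adipose tissue;
#' \item painful vs non-painful neuromas — the same eight contrasts;
#' \item Spearman correlations with NRS over the neuroma samples —
#'   relative unorganized, relative organized, and the normalized
#'   deviation index (samples with an undefined index excluded);
#' \item exploratory: Spearman of age vs NRS and Mann-Whitney of NRS by
#'   sex, over the neuroma samples.
#' }
#' Raw p-values are reported; a Benjamini-Hochberg adjusted column is
#' appended when `bh_adjust = TRUE`. Rows whose inputs are degenerate
#' (e.g. all-equal NRS) are flagged `not computable` rather than dropped.
#'
#' @param compositions data.frame from [composition_table()].
#' @param records cohort records matching `compositions$sample_id`.
#' @param force_nonparametric route every group comparison to
#'   Mann-Whitney.
#' @param welch use Welch instead of Student on parametric branches.
#' @param bh_adjust append a BH-adjusted p-value column.
#' @return object of class `nm_report`: list with `results` (data.frame),
#'   `config` echo and `n_samples`.
#' @export
run_full_analysis <- function(compositions, records,
                              force_nonparametric = FALSE,
                              welch = FALSE, bh_adjust = FALSE) {
  missing <- setdiff(records$sample_id, compositions$sample_id)
  if (length(missing))
    stop("missing composition for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- merge(records, compositions, by = "sample_id")
  grp <- function(g) df[df$group %in% g, , drop = FALSE]
  neuroma <- grp(c("nonpainful_neuroma", "painful_neuroma"))
  rows <- list()
  vars <- c(rel_unorganized = "rel_unorganized_nervous",
            rel_organized = "rel_organized_nervous",
            rel_connective = "rel_connective",
            rel_adipose = "rel_adipose",
            abs_unorganized = "abs_unorganized_nervous_mm2",
            abs_organized = "abs_organized_nervous_mm2",
            abs_connective = "abs_connective_mm2",
            abs_adipose = "abs_adipose_mm2")
  for (v in names(vars)) {
    rows[[paste0("ctrl_vs_neuroma_", v)]] <- safe_stat({
      r <- compare_groups(grp("control")[[vars[[v]]]],
                          neuroma[[vars[[v]]]],
                          force_nonparametric = force_nonparametric,
                          welch = welch, variable = v,
                          comparison = "control_vs_neuroma")
      r
    })
    rows[[paste0("painful_vs_nonpainful_", v)]] <- safe_stat({
      compare_groups(grp("painful_neuroma")[[vars[[v]]]],
                     grp("nonpainful_neuroma")[[vars[[v]]]],
                     force_nonparametric = force_nonparametric,
                     welch = welch, variable = v,
                     comparison = "painful_vs_nonpainful")
    })
  }
  corr_vars <- c(rel_unorganized = "rel_unorganized_nervous",
                 rel_organized = "rel_organized_nervous",
                 deviation_index = "deviation_index")
  for (v in names(corr_vars)) {
    rows[[paste0("nrs_", v)]] <- safe_stat({
      d <- neuroma[!is.na(neuroma[[corr_vars[[v]]]]), , drop = FALSE]
      spearman_correlation(d[[corr_vars[[v]]]], d$nrs, variable = v,
                           comparison = "vs_nrs_neuromas")
    })
  }
  rows[["nrs_age"]] <- safe_stat(
    spearman_correlation(neuroma$age, neuroma$nrs, variable = "age",
                         comparison = "vs_nrs_neuromas"))
  rows[["nrs_sex"]] <- safe_stat({
    m <- neuroma$nrs[neuroma$sex == "male"]
    f <- neuroma$nrs[neuroma$sex == "female"]
    compare_groups(m, f, force_nonparametric = TRUE, variable = "sex",
                   comparison = "nrs_by_sex_neuromas")
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res <- cbind(analysis = names(rows), res)
  # fill the label columns that safe_stat left blank
  res$variable[is.na(res$variable)] <- res$analysis[is.na(res$variable)]
  res$significance <- annotate_significance(res$p_value)
  if (bh_adjust)
    res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  structure(list(
    results = res,
    config = list(force_nonparametric = force_nonparametric,
                  welch = welch, bh_adjust = bh_adjust),
    n_samples = nrow(df)
  ), class = "nm_report")
}

#' @export
print.nm_report <- function(x, ...) {
  cat("Cohort analysis report (", x$n_samples, " samples)\n", sep = "")
  cols <- c("analysis", "test_name", "statistic", "p_value", "significance")
  print(x$results[, cols], digits = 3)
  invisible(x)
}
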