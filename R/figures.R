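# Violin and scatter figures for the cohort report. Figures are
# best-effort artifacts: a failure to draw one is logged, never fatal.

# internal: long-format composition data for one comparison
comparison_long <- function(compositions, records, groups_a, groups_b,
                            label_a, label_b) {
  df <- merge(records, compositions, by = "sample_id")
  vars <- c(rel_unorganized = "rel_unorganized_nervous",
            rel_organized = "rel_organized_nervous",
            rel_connective = "rel_connective",
            rel_adipose = "rel_adipose")
  out <- do.call(rbind, lapply(names(vars), function(v) {
    data.frame(variable = v,
               arm = ifelse(df$group %in% groups_a, label_a,
                            ifelse(df$group %in% groups_b, label_b, NA)),
               value = df[[vars[[v]]]],
               stringsAsFactors = FALSE)
  }))
  out[!is.na(out$arm), , drop = FALSE]
}

# internal: violin panel with median dot, IQR bar and significance stars
violin_panel <- function(long, stars, title) {
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80", color = "grey40",
                         scale = "width", trim = FALSE) +
    ggplot2::stat_summary(fun = stats::median, geom = "point",
                          color = "white", fill = "white", size = 2.5,
                          shape = 21) +
    ggplot2::stat_summary(
      fun.min = function(z) stats::quantile(z, 0.25),
      fun.max = function(z) stats::quantile(z, 0.75),
      geom = "linerange", linewidth = 1.4) +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(x = 1.5, y = Inf, label = .data$sig),
                       vjust = 1.5, size = 6, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(title = title, x = NULL, y = "fraction of tissue area") +
    ggplot2::theme_minimal()
}

#' Render report figures
#'
#' Violin plots (median dot, IQR bar, asterisk annotations: * for
#' p < 0.05, ** for p < 0.01) for the two group comparisons, and
#' NRS scatter panels with the Spearman rho and p for the three pain
#' correlations. Failures are logged and skipped.
#'
#' @param report `nm_report` from [run_full_analysis()].
#' @param compositions composition table used for the report.
#' @param records matching cohort records.
#' @param out_dir output directory for PNG files.
#' @return character vector of files written, invisibly.
#' @export
render_figures <- function(report, compositions, records, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  written <- character(0)
  save_fig <- function(plot, name, width = 7, height = 5) {
    f <- file.path(out_dir, name)
    tryCatch({
      ggplot2::ggsave(f, plot, width = width, height = height, dpi = 120)
      written <<- c(written, f)
    }, error = function(e)
      message("figure ", name, " skipped: ", conditionMessage(e)))
  }
  star_df <- function(comparison) {
    sel <- res$comparison %in% comparison &
      res$variable %in% c("rel_unorganized", "rel_organized",
                          "rel_connective", "rel_adipose")
    data.frame(variable = res$variable[sel],
               sig = res$significance[sel], stringsAsFactors = FALSE)
  }
  save_fig(violin_panel(
    comparison_long(compositions, records, "control",
                    c("nonpainful_neuroma", "painful_neuroma"),
                    "control", "neuroma"),
    star_df("control_vs_neuroma"),
    "Control nerves vs neuromas: relative tissue areas"),
    "violin_control_vs_neuroma.png")
  save_fig(violin_panel(
    comparison_long(compositions, records, "painful_neuroma",
                    "nonpainful_neuroma", "painful", "non-painful"),
    star_df("painful_vs_nonpainful"),
    "Painful vs non-painful neuromas: relative tissue areas"),
    "violin_painful_vs_nonpainful.png")

  df <- merge(records, compositions, by = "sample_id")
  df <- df[df$group != "control", , drop = FALSE]
  corr_vars <- c(nrs_rel_unorganized = "rel_unorganized_nervous",
                 nrs_rel_organized = "rel_organized_nervous",
                 nrs_deviation_index = "deviation_index")
  for (an in names(corr_vars)) {
    row <- res[res$analysis == an, ]
    sub <- if (nrow(row) == 1 && !is.na(row$p_value))
      sprintf("Spearman r = %.2f, p = %.3g %s", row$statistic,
              row$p_value, row$significance) else "not computable"
    v <- corr_vars[[an]]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nrs, y = .data[[v]])) +
      ggplot2::geom_point(size = 2.5, alpha = 0.8) +
      ggplot2::labs(title = paste0(v, " vs pain (NRS), neuroma samples"),
                    subtitle = sub, x = "NRS", y = v) +
      ggplot2::theme_minimal()
    save_fig(p, paste0("scatter_", an, ".png"), width = 5, height = 4)
  }
  invisible(written)
}
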