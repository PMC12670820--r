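#!/usr/bin/env Rscript
# Stage 4 — group comparisons and pain correlations.
# Normality-gated control-vs-neuroma and painful-vs-non-painful contrasts
# over relative and absolute areas, plus Spearman correlations of the
# organized fraction, unorganized fraction and deviation index with NRS.

suppressMessages({ library(optparse); library(neuromorph) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results")
)))

rec <- read_cohort_table(file.path(opts$outdir, "cohort", "cohort.csv"))
comp <- read.delim(file.path(opts$outdir, "compositions.tsv"))
report <- run_full_analysis(comp, rec)
write_results(comp, report, opts$outdir)

print(report)
res <- report$results
key <- res[res$analysis %in% c("ctrl_vs_neuroma_rel_unorganized",
                               "painful_vs_nonpainful_rel_organized",
                               "nrs_rel_organized",
                               "nrs_deviation_index"), ]
cat("\nHeadline findings:\n")
for (i in seq_len(nrow(key)))
  cat(sprintf("  %-36s %-15s stat=%8.3f  p=%.3g %s\n",
              key$analysis[i], key$test_name[i], key$statistic[i],
              key$p_value[i], key$significance[i]))
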