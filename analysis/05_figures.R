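#!/usr/bin/env Rscript
# Stage 5 — violin and scatter figures with significance annotations.

suppressMessages({ library(optparse); library(neuromorph) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results")
)))

rec <- read_cohort_table(file.path(opts$outdir, "cohort", "cohort.csv"))
comp <- read.delim(file.path(opts$outdir, "compositions.tsv"))
report <- run_full_analysis(comp, rec)
figs <- render_figures(report, comp, rec, file.path(opts$outdir, "figures"))
cat("Wrote", length(figs), "figures:\n")
cat(paste(" ", figs, collapse = "\n"), "\n")
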