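#!/usr/bin/env Rscript
# Stage 2 — train the random-forest pixel classifier.
# Uses the ground-truth masks of one sample per group as the annotation
# stand-in (capped pixels per class, mirroring sparse ROI annotation) and
# reports the held-out pixel accuracy.

suppressMessages({ library(optparse); library(neuromorph) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 42L),
  make_option("--outdir", type = "character", default = "results")
)))

cohort_dir <- file.path(opts$outdir, "cohort")
rec <- read_cohort_table(file.path(cohort_dir, "cohort.csv"))
train_ids <- rec$sample_id[!duplicated(rec$group)]
cat("Training on:", paste(train_ids, collapse = ", "), "\n")

images <- lapply(train_ids, function(id)
  read_image(file.path(cohort_dir, paste0(id, "_image.png"))))
masks <- lapply(train_ids, function(id)
  read_mask(file.path(cohort_dir, paste0(id, "_mask.png"))))
names(images) <- train_ids

model <- train_classifier(images, masks, seed = opts$seed,
                          max_pixels_per_class = 10000)
print(model)
save_model(model, file.path(opts$outdir, "model.rds"))
cat("Model written to", file.path(opts$outdir, "model.rds"), "\n")
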