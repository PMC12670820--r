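# neuromorph

Machine-learning morphometry of peripheral-nerve histology: does the
internal architecture of a neuroma predict how much it hurts?

After nerve transection, regenerating axons that fail to reach their
target form a neuroma — a disorganized mass of mini-fascicles and
connective tissue — yet only some neuromas are painful. `neuromorph`
implements a quantitative histology pipeline for testing whether the
*preservation of organized fascicular tissue* inside a nerve
cross-section is associated with patient-reported pain (NRS 0–10):

1. **Pixel classification.** A random forest is trained on ROI-annotated
   pixels of EvG-stained cross-section images and predicts, per pixel, a
   six-channel probability map over background, organized nervous tissue
   (intact round fascicles), unorganized nervous tissue (neuroma),
   connective tissue, adipose tissue and erythrocytes.
2. **Roundness reclassification.** Connected nervous-tissue components
   are relabeled wholesale by their circularity
   `C = 4πA / P²` — components with `C ≥ 0.6` are organized fascicles,
   the rest neuroma tissue; sub-fascicle speckle (< 50 px) is returned to
   connective tissue.
3. **Composition and deviation index.** Per sample, relative and
   absolute areas per class, and the normalized deviation index
   `(unorganized − organized) / max(unorganized, organized)` ∈ [−1, 1],
   where −1 means purely organized (control-like) and +1 purely
   unorganized nervous tissue.
4. **Cohort statistics.** Kolmogorov–Smirnov (Lilliefors) normality
   gating into Student's *t* or Mann–Whitney *U* (exact, tie-aware, for
   pooled n ≤ 12) for control-vs-neuroma and painful-vs-non-painful
   contrasts, and Spearman correlations of the composition measures with
   NRS.

Because clinical slides cannot ship with a package, `neuromorph`
includes a **synthetic cohort generator** that renders EvG-like nerve
cross-sections with exact ground-truth masks and a 12-sample clinical
table (4 controls, 3 non-painful neuromas, 5 painful neuromas with NRS
5, 6, 7, 8, 8), encoding a monotone negative coupling between pain and
the organized fraction. Every stage of the pipeline is therefore
testable end-to-end, with known truth, offline.

## Worked example

```r
library(neuromorph)

pl <- run_pipeline(default_cohort_spec(), seed = 11)
pl
#> neuromorph pipeline run: 12 samples, seed 11
#>   mean pixel accuracy: 0.9992
#>   max |organized fraction error|: 0.000667
#>   nrs_rel_organized: rho = -0.970, p = 6.7e-05
#>   nrs_deviation_index: rho = 0.970, p = 6.7e-05
```

The forest recovers the ground-truth masks almost perfectly (mean pixel
accuracy 0.9992 across the 12 samples), the refined relative organized
fraction matches the generator's truth to < 0.001, and the report
reproduces both encoded clinical effects over the neuroma samples: the
relative amount of organized nervous tissue falls with pain
(Spearman rho = −0.97) and the deviation index rises with pain
(rho = +0.97), both p < 0.001.

The same run as separate stages, writing artifacts under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 42      # images + masks + metadata
Rscript analysis/02_train.R    --seed 42      # forest + held-out accuracy
Rscript analysis/03_segment_quantify.R        # refined masks + compositions.tsv
Rscript analysis/04_stats.R                   # stats_report.json + highlights
Rscript analysis/05_figures.R                 # violin / scatter figures
```

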