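---
title: "Methods: machine-learning morphometry of nerve cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: machine-learning morphometry of nerve cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameters and
design choices: what each stage computes, why the defaults are what they
are, what the synthetic data does and does not emulate, and where the
numerical corners are.

## The measurement problem

A transected peripheral nerve that fails to re-innervate its target
forms a neuroma: a bulbous mass in which regenerating axons grow as
small, irregular *mini-fascicles* embedded in connective tissue, instead
of the large round fascicles of intact nerve. The package quantifies,
from a stained cross-section image, how much of the nervous tissue
retains organized fascicular form, and relates that quantity to the
patient's pain score (NRS, an integer 0–10). The analytical chain is:
per-pixel tissue classification → shape-based correction of the
organized/unorganized split → per-sample composition → cohort
statistics.

## Tissue classes

Six classes with a fixed integer coding shared package-wide
(`tissue_classes()`): background (0), organized nervous tissue (1),
unorganized nervous tissue (2), connective tissue (3), adipose tissue
(4), erythrocytes (5). The probability map of the classifier has exactly
these six channels, in this order. Training masks additionally use the
sentinel 255 for unannotated pixels, which is *not* a class: background
is trainable tissue context, absence of annotation is absence of
information.

## Pixel classifier

**Features.** The image is described per pixel by ilastik-style
color/texture features (`feature_config()`): the raw RGB values, plus —
at Gaussian scales σ ∈ {1, 2, 4, 8} px — the smoothed color, the
gradient magnitude, and the local variance
(`E[x²] − E[x]²` under the same Gaussian window), each per channel:
3 + 3·4·3 = 39 channels. Boundary handling is reflective (mirror
padding). Gradients are computed as central differences of the raw
channels and smoothed afterwards; since differentiation and Gaussian
smoothing commute this is equivalent to differentiating the smoothed
image, and it guarantees exactly zero gradient features on a constant
image. Negative variance from floating-point cancellation is clamped to
zero.

**Forest.** A probability random forest (`ranger`, 100 trees, unlimited
depth, single-threaded for determinism, mandatory seed). Class imbalance
is handled by capping each class at `max_pixels_per_class` training
pixels rather than by class weights — reproducible and simple.
Candidate pixels are ordered by (image name, row, column) before the
seeded subsample, so training is invariant to the order in which images
are supplied. A stratified 10% split is held out to report pixel
accuracy; classes with fewer than 10 labeled pixels stay in the training
split (a 1-pixel class cannot be split meaningfully).

**Prediction.** Images are processed in square tiles (default side
1024 px) with 32 px of context on each side, bounding memory for
arbitrarily large inputs; each pixel takes its prediction from the tile
whose core contains it. Hardening to labels is per-pixel argmax with
ties broken toward the lower class index — a documented, deterministic
convention whose only practical consequence is that a perfectly
uninformative pixel becomes background.

## Roundness reclassification

The classifier separates tissue by color and texture, but the
organized/unorganized distinction is ultimately *morphological*: intact
fascicles are round. Post-processing therefore re-derives that split
from shape. Connected components are formed over the union of the two
nervous classes (8-connectivity by default), and each component is
relabeled wholesale — the fascicle, not the pixel, is the unit of
decision:

* circularity `C = 4πA/P² ≥ 0.6` → organized fascicle;
* `C < 0.6` → unorganized (neuroma) tissue;
* components below `min_component_px = 50` px → connective tissue
  (classifier speckle, not a mini-fascicle; set 0 to disable).

**Circularity details.** `A` is the pixel count. `P` is the length of
the outer boundary estimated from the Moore chain code with
corner-corrected weights (0.980 per axis step, 1.406 per diagonal step,
−0.091 per direction change), plus π for the half-pixel offset between
the pixel-center contour and the boundary of the digitized set. This
estimator is nearly unbiased across the shapes that matter here: a
rasterized disk of radius 100 measures C ≈ 0.995, a 100×100 square
C ≈ 0.82 (continuum value π/4 ≈ 0.785), a 1×100 bar C ≈ 0.03. A plain
Crofton line-intercept estimator was rejected because its square bias
(C ≈ 0.87) would sit too close to plausible threshold settings. The
result is clamped to [0, 1]; a single-pixel component is defined to have
roundness 1 (its shape carries no information, and it is in any case
far below the size floor). Boundary tracing terminates by state-cycle
detection — the classic "revisit the start pixel" criterion livelocks
on one-pixel-wide components.

**Threshold.** 0.6 sits midway between the circularities the generator
guarantees by construction (fascicle ellipses ≥ 0.7 at axis ratio
≥ 0.78; star-shaped blobs ≤ 0.5) and is configurable
(`morphometry_config()`), since on real slides the separating value
would be a calibration question.

## Composition and the deviation index

Relative area per class = class pixels / all non-background pixels
("fraction of total tissue area"); erythrocytes are included in the
denominator by default, with a flag to exclude them. Absolute area =
pixels × mpp² / 10⁶, in mm², with mpp the microns-per-pixel of the
slide. The normalized deviation index
`(u − o)/max(u, o)` summarizes the organized/unorganized balance on a
fixed [−1, 1] scale: −1 purely organized (control-like), +1 purely
unorganized. It is scale-invariant and antisymmetric. When `u = o = 0`
the formula is 0/0 and the index is **undefined** (`NA`), not zero:
coding the degenerate case as mid-scale would fabricate a balance the
sample does not have. Undefined indices are excluded from correlations.

## Statistical stage

The report (`run_full_analysis()`) covers, mirroring the clinical
analysis design: control vs pooled neuromas and painful vs non-painful,
each for relative and absolute areas of the four structural tissue
classes; Spearman correlations with NRS (over neuroma samples) for
relative unorganized, relative organized, and the deviation index; and
exploratory age and sex associations.

* **Normality gate.** Lilliefors-type KS (estimated mean/SD,
  `nortest::lillie.test`), flag normal at p > 0.05. Estimated-parameter
  KS is the defensible reading when no reference distribution is stated;
  it is swappable.
* **Routing.** Degenerate (zero-variance) groups — e.g. unorganized
  areas in controls, which are structurally ~0 — and groups with n < 4
  (normality unverifiable) go to Mann–Whitney, as does anything failing
  the gate; otherwise Student's equal-variance *t* (the conventional
  reading of "t-test for independent samples"), with a Welch flag.
* **Mann–Whitney.** Mid-rank U. For pooled n ≤ 12 the two-sided p is
  computed by complete enumeration of group assignments — exact even
  under ties, which base `wilcox.test` does not offer (it remains the
  tie-free cross-check in the tests). The null distribution of U is
  symmetric about n₁n₂/2 under exchangeability regardless of ties, so
  the two-sided p is the probability of |U − n₁n₂/2| at least as large
  as observed. Above n = 12, the tie-corrected normal approximation with
  continuity correction.
* **Spearman.** Pearson correlation of mid-ranks; two-sided p from the
  t approximation with n − 2 df; optional seeded permutation p. With
  n = 8 neuroma samples and heavy ties in NRS the t approximation is
  only approximate — the null-calibration test below checks that its
  size stays in a sane band under this exact tie structure.
* Raw p-values are reported (no correction by default; a
  Benjamini–Hochberg column is optional), medians/IQRs use the
  linear-interpolation quantile, and figures annotate * for p < 0.05,
  ** for p < 0.01.

## The synthetic cohort

The generator exists so that every downstream stage has exact ground
truth. Its defaults are the study conditions, not tuning knobs.

**Clinical table.** 12 samples: 4 controls, 3 non-painful neuromas
(NRS 0 by definition of the group), 5 painful neuromas with NRS
{5, 6, 7, 8, 8} — the minimal integer multiset with median 7 and range
5–8 for n = 5, fixed deterministically. Ages and sexes are fixed sets
matching the emulated cohort's group summaries (e.g. painful median age
32, range 23–61, 4 male / 1 female) and are uninformative about pain
beyond group membership.

**Effect encoding.** The fraction of nervous pixels drawn as organized
fascicles is 0.9 for controls, 0.6 for non-painful neuromas, and for
painful neuromas interpolates linearly from 0.30 (NRS 5) down to 0.10
(NRS 8), plus per-sample Gaussian jitter (sd 0.02, clamped to
[0.02, 0.98]). This makes pain and fascicular disorganization
monotonically coupled — the direction the statistics stage is expected
to recover — while the jitter prevents the coupling from being exactly
deterministic. `sample_organized_fractions()` exposes this stage
without rendering, which is how the null-calibration Monte Carlo (all
group targets equal) checks the Spearman test's size cheaply.

**Rendering.** On a 512² canvas (mpp default 2 µm/px, so a cross-section
of roughly 1 mm — a plausible digitized-nerve scale): an elliptical
nerve (bulbous for neuromas: semi-axis 0.43–0.47 of the canvas vs
0.33–0.37 for controls) filled with connective matrix; organized
fascicles as rotated ellipses (axis ratio ≥ 0.78, circularity ≥ 0.7 by
construction) kept ≥ 2 px clear of everything so each is a single
component; unorganized tissue as clustered star-shaped blobs (radial
cosine spikes, circularity ≤ 0.5 by construction) free to merge with
each other but kept off the fascicles; adipose as round pale vacuoles;
erythrocytes as small red specks. The absolute adipose budget is
group-independent while the neuroma cross-section is larger, so the
*relative* adipose fraction falls in neuromas — the same arithmetic
that produces that contrast in real bulbous neuromas. Organized pixels
are placed to the per-sample target and unorganized pixels to the
matching ratio, so the achieved organized fraction tracks the target to
well within the ±0.1 contract. Packing failures (targets that do not
fit the canvas) raise errors naming the failing class.

**Appearance.** Each class has a fixed base color in an invented
EvG-like palette (collagen pink-red, nervous tissue yellow-tan,
erythrocytes saturated red, adipose warm white, background cool
off-white; `evg_palette()`), plus shared band-limited texture (Gaussian
field, σ 3 px), a random low-frequency illumination ramp (6–12/255),
and i.i.d. Gaussian pixel noise (default sd 8/255). The noise model is
deliberately the cheapest one that defeats a pure color-lookup
classifier; at the default noise the forest still reaches ~0.999 pixel
accuracy, and a monotone-learnability test checks that accuracy does
not improve as noise grows to 64/255.

**What this does and does not show.** Passing end-to-end tests on this
generator demonstrates that the *pipeline machinery* — features, forest,
shape filter, composition, statistics — correctly recovers a known
ground truth and a known direction of effect at clinical cohort size.
It does not demonstrate stain-robust segmentation of real EvG slides:
real tissue has within-class texture structure, stain variation,
sectioning artifacts, intrafascicular connective tissue and ambiguous
boundaries that no additive-noise palette model emulates. Claims about
real slides require real annotated slides.

## Determinism and problem sizes

Every stochastic step (rendering, subsampling, forest growth, held-out
split, permutations) is seeded; per-sample render seeds derive
deterministically from the cohort seed and stay inside 32-bit range.
Rendering the same (spec, record, seed) twice is bit-identical, as is
regenerating a cohort directory.

One seeding rule deserves emphasis: Monte-Carlo replicates are drawn
from a *single* seeded stream (`sample_organized_fractions(seed =
NULL)` inside one `set.seed()`), never by reseeding with consecutive
small integers — consecutive Mersenne–Twister initializations at small
seeds are correlated enough to collapse hundreds of nominal replicates
into a few distinct rank patterns, which visibly distorts measured
test levels at n = 8.

The shipped analyses use 512² images for the cohort pipeline (about two
minutes per 12-sample cohort end-to-end on one core) and 256² for
component-level tests; these sizes were chosen as the smallest canvases
on which fascicle geometry is comfortably resolved — a fascicle of
radius ~20 px still has ~100 boundary steps, plenty for stable
circularity. The null-calibration Monte Carlo runs 200 cohorts at the
fraction level (no rendering), and the parameter-recovery check 100.

## Known limitations

* "Roundness" is circularity with one global threshold; elongated but
  perfectly healthy fascicles (oblique sections) would be demoted. A
  convexity- or solidity-based filter could be swapped in via
  `morphometry_config()`.
* The reclassification is wholesale per component; a fascicle fused to
  neuroma tissue in the predicted mask is decided as one unit.
* The exact Mann–Whitney enumerates `choose(n, n₁)` assignments — fine
  to n = 12, combinatorial beyond; the implementation switches to the
  normal approximation there.
* Spearman p-values at n = 8 with tied NRS rest on the t approximation;
  the permutation option exists where exactness matters.
* The generator draws no intrafascicular connective tissue, no myelin
  substructure, no stain gradients within a class; see above for what
  that implies about external validity.
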