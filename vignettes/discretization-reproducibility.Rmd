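---
title: "Gray-level discretization and the reproducibility of 2D texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-level discretization and the reproducibility of 2D texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiomics pipelines routinely reduce their feature space by keeping only
features that are *reproducible* across observers: a feature whose value
changes materially when a different radiologist outlines the same lesion is
a poor biomarker candidate. Before any texture feature can be computed, the
continuous pixel intensities inside the region of interest (ROI) must be
discretized to a small set of integer gray levels, and the field uses two
conventions:

* **Fixed bin size (FBS, "absolute")** — a bin boundary every `BS` intensity
  units, anchored at zero:
  `I_BS(x) = ceil(I(x)/BS) - min(ceil(I(x)/BS)) + 1`.
* **Fixed bin number (FBN, "relative")** — the ROI's own intensity range is
  split into `BN` equal bins: the ROI minimum maps to level 1 and any other
  intensity to `ceil(BN * (I(x) - min I) / (max I - min I))`.

The two differ in what they are sensitive to. FBN depends on the ROI's
min/max, so a slightly different delineation that includes a darker
background pixel re-bins *every* pixel. FBS depends only on absolute
intensities: changing the delineation can only shift all levels by a common
constant. This package implements both rules, the downstream texture
machinery, the reproducibility selection rule, and a synthetic-study
generator, so the effect of the discretization convention on
inter-/intra-observer feature reproducibility can be studied end to end.

## Pipeline overview

1. **Synthetic study** (`dataset_spec()`, `generate_study()`): images with
   elliptical textured lesions on sequence-specific intensity scales; three
   session masks per ROI (reader 1, reader 2 twice) whose overlap is tuned
   to target Dice coefficients.
2. **Discretization** (`fbs_discretize()`, `fbn_discretize()`,
   `discretize_roi()`): the two rules above; grids under study are six bin
   sizes (1, 5, 10, 20, 25, 50) and eight bin numbers (8, 16, ..., 1024).
3. **Texture matrices and features** (`texture_matrices()`,
   `compute_features()`, `extract_roi_features()`): GLCM, GLRLM, GLSZM,
   GLDM and NGTDM with two aggregation conventions.
4. **Reproducibility selection** (`icc_a_k()`, `lin_ccc()`,
   `select_reproducible()`): two-way random-effects absolute-agreement
   average-measures ICC on all session pairs (threshold 0.8, strict) and
   Lin's concordance coefficient on the repeated-reader pair (threshold
   0.9, strict).
5. **Experiments** (`run_grid()`, `dice_curve()`,
   `simulate_delineations()`): per-sequence best-setting comparison of FBS
   vs FBN by exact Fisher test, within-grid chi-square homogeneity, and
   reproducible-feature counts as a function of delineation overlap.

```{r}
library(texrepro)

spec <- dataset_spec(seed = 1)       # 37 patients x 2 regions x 6 sequences
study <- generate_study(spec)        # 444 ROIs per reading session
grid <- discretization_grid()        # 6 FBS + 8 FBN settings
experiment <- run_grid(study, grid)
glance(experiment)                   # per sequence: best FBS/FBN, p-values
autoplot(experiment)
```

## The synthetic data generator

The MRI datasets the reading design derives from are not public, so the
generator emulates their *structure*, not their content:

* **Layout.** 37 patients x 2 regions x 6 sequences = 444 ROIs per reading
  session by default; a 30-patient x 1 region x 1 sequence spec emulates a
  single-sequence breast-lesion dataset.
* **Texture.** Lesions are filled with a Gaussian random field — white
  noise smoothed with a Gaussian kernel whose row/column correlation
  lengths are drawn per ROI around `texture_correlation_length` (default
  3 px, per-axis factors 0.5-2) — passed through a Gaussian CDF and mapped
  affinely into a per-ROI sub-range of the sequence's intensity range. The
  per-ROI coarseness and anisotropy carry the between-subject variance
  that reproducibility coefficients compare against, including variance
  that survives range-normalizing discretization. The texture model is a
  stand-in: no claim is made that its higher-order statistics match
  glandular tissue.
* **Background and halo.** Surrounding tissue sits at moderate contrast
  (mean 0.25 of the sequence range, noise SD 0.01) with a partial-volume
  halo decaying exponentially (width 8 px) from the lesion edge. The halo
  is what makes the relative-discretization mechanism *graded*: a shallow
  delineation excursion picks up intensities just below the lesion
  minimum, a deep one reaches darker tissue, so the ROI-range shift — and
  with it the FBN re-binning error — grows with the severity of the
  delineation disagreement instead of saturating at the first included
  background pixel. These background parameters are not characterized by
  any reference data; they were fixed once to give partial (rather than
  total) degradation of relative-discretization reproducibility at high
  Dice, the regime reported for real delineations.
* **Intensity scales.** Each "sequence" has its own intensity range
  (defaults between 0-800 and 0-3000), emulating the arbitrary units of
  weighted MR sequences. The ADC-like sequence uses scanner storage units
  (0-3000, i.e. 1e-6 mm^2/s) rather than physical 1e-3 mm^2/s values: that
  is the scale on which clinical ADC maps are exported and on which
  absolute bin sizes of 1-50 are meaningful.
* **Delineation variability.** Session masks are elastic deformations of
  the reference: a Gaussian-smoothed random displacement field (sigma 6 px)
  applied with nearest-neighbour re-binarization. Per ROI, the displacement
  amplitude is found by bisection so the mask's Dice with the reference
  hits a per-ROI target drawn around `reader_dice_target` (default 0.84,
  the study-level mean inter-reader overlap). The two reader-2 sessions use
  correlated fields (`rho = 1 - ((1-intra)/(1-inter))^2 / 2`, about 0.875
  at the defaults), which lands the intra-observer mean Dice near its 0.92
  target; both achieved means are checked against a +/-0.03 tolerance and
  generation fails loudly otherwise.
* **Determinism.** All randomness flows from one integer seed through named
  substreams (per-ROI image, reader-2 fields, candidate streams), so a
  study regenerates bit-identically.

What passing tests on these data do show: the *mechanism* by which relative
discretization amplifies delineation variability (min/max sensitivity) and
the directional consequences for feature selection. What they do not show:
effect sizes on real MR tissue, scanner noise, field inhomogeneity, or
reader-specific bias (the simulated "readers" differ only in overlap, not
in systematic style).

## Texture features and aggregation

Two feature configurations are provided:

* `"full"` (69 features): GLCM 23, GLRLM 16, GLSZM 16, GLDM 14 — the
  default set of a widely used Python extraction library, with the maximal
  correlation coefficient omitted from the GLCM family.
* `"inhouse"` (57 features): GLCM 26 (the 23 above plus Dissimilarity, Sum
  Variance and the maximal correlation coefficient), GLRLM 13 and GLSZM 13
  (the classic lists without the normalized non-uniformities and entropy),
  NGTDM 5 (Coarseness, Contrast, Busyness, Complexity, Strength).

Matrix conventions: GLCM symmetric, distance 1, the four unique 2D
directions; GLRLM along the same four directions; GLSZM and GLDM
8-connected; GLDM dependence tolerance `alpha = 0`; NGTDM over the
8-neighbourhood. Matrices are stored sparsely (level, second index, count),
which is exact for every implemented feature and keeps 1024-bin settings
cheap.

Aggregation over directions follows the two conventions encountered in
extraction software:

* `per_angle_average` — normalize each directional matrix, compute the
  feature per direction, average the four values (the `"full"` default);
* `merged_weighted` — sum the four *unnormalized* matrices, weighting the
  diagonal directions by `sqrt(2)`, then compute the feature once (the
  `"inhouse"` default).

Degenerate cases are deliberate choices: a constant ROI discretizes to a
single level under FBN (the division by zero range is short-circuited to
level 1); an all-zero matrix yields `NA` features, and an `NA` coefficient
downstream can never mark a feature reproducible.

## Numerical and statistical choices

* **ICC.** `icc_a_k()` implements the two-way random-effects,
  absolute-agreement, *average-measures* form
  `(MSR - MSE) / (MSR + (MSC - MSE)/n)` from the closed-form mean squares;
  sessions are compared pairwise (k = 2) on each of the three session
  pairs. The single-measures form is available via `type = "single"` for
  sensitivity analysis. Thresholds are strict: an ICC of exactly 0.8 or a
  CCC of exactly 0.9 is rejected.
* **CCC.** `lin_ccc()` uses moment (1/n) estimators,
  `2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)`.
* **Fisher test.** `fisher_exact_2x2()` enumerates the hypergeometric
  distribution over the observed margins and sums the probabilities not
  exceeding the observed table's (two-sided); a zero margin returns 1.
  The best-FBS vs best-FBN table is `{best FBS, best FBN} x {selected,
  not selected}` over the common feature set.
* **Chi-square.** `chisq_homogeneity()` is the Pearson test without
  continuity correction on the settings x selected/not table, reported
  separately within the FBS grid and the FBN grid; it acts on selection
  *counts*, not on feature-wise selection patterns.
* **Ties.** When two settings select equally many features, the smaller
  bin parameter is reported as "best".
* **Intensity normalization** (`normalize_intensity()`, off by default)
  centres by the mean, scales by the population SD, *clips* values beyond
  +/-3 SD, shifts to non-negative and rescales to the original range.
  Clipping (rather than removing pixels) preserves the ROI geometry on
  which run/zone statistics depend; this is an interpretation of an
  "exclusion" step whose exact meaning is underdetermined, and it is not
  applied to ADC-like maps.

## Delineation simulation

`simulate_delineations()` draws `n_candidates` (default 5000) perturbed
masks — a binary opening and/or closing with disc radii drawn from 0-3 px,
in random order, then an elastic deformation with amplitude drawn from
0-18 px — computes each candidate's Dice with the reference, and keeps one
uniformly drawn candidate per half-open Dice interval `[lo, lo + 0.05)`
for `lo` in 0.65-0.95 (seven masks; Dice 1.0 is the untransformed
reference). Candidates whose area leaves `[0.4, 2.5]` times the reference
area are discarded and redrawn, replacing the visual plausibility check a
human would perform. The composition order of the morphological and
elastic steps is a documented choice; the perturbation family only needs to
*cover* the Dice range, and the default amplitudes do so for lesion-sized
masks (the candidate population spans below 0.65 and above 0.95 on a
30-px-radius disk). An empty bin raises an error naming the bin.

## Problem sizes used in the shipped checks

The package's own test suite exercises the full default layout (444 ROIs)
for the structural counts and runs the comparative experiments at reduced
but statistically meaningful sizes, chosen so the whole suite completes in
minutes on a single core: the grid-direction check uses 14-patient studies
(28 ROIs per sequence, all 6 sequences) over three seeds with a
two-settings-per-method grid (bin sizes 5 and 20, bin numbers 64 and 512,
spanning each method's small/large regime); the Dice-curve check uses a
12-patient, 2-sequence study with 250 candidates per ROI. These sizes are
the package's choices for routine verification; all of them scale up by
changing `dataset_spec()` and `perturbation_config()` arguments.

## Known limitations

* 2D single-slice only, matching the delineation protocol it emulates; no
  3D texture matrices.
* No MR physics: no Rician noise, bias field, or resampling; the generator
  tests the discretization mechanism, not acquisition effects.
* The exact membership of the historical 23- and 26-feature GLCM lists is
  not recoverable from the feature *counts* alone; the package fixes a
  documented, standard-nomenclature list of each size.
* Shape and first-order families are out of scope (texture only), as are
  filtered (wavelet/LoG) feature classes and histogram-equalization
  discretization variants.
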