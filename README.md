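# texrepro

Gray-level discretization and the reproducibility of 2D MRI texture
radiomics features.

## The problem

Radiomics studies reduce their feature space by keeping only features that
are *reproducible* across readers: a texture statistic whose value changes
when a different radiologist outlines the same lesion cannot serve as an
imaging biomarker. Every texture feature, however, is computed only after
the ROI's continuous intensities have been discretized to integer gray
levels, and the two standard conventions behave very differently under
delineation variability:

* **Fixed bin size (FBS, absolute):** `I_BS(x) = ⌈I(x)/BS⌉ − min ⌈I(x)/BS⌉ + 1`
  — a bin every `BS` intensity units, anchored at 0. Changing the
  delineation can only shift all levels by a common constant.
* **Fixed bin number (FBN, relative):**
  `I_BN(x) = ⌈BN·(I(x) − min I)/(max I − min I)⌉` (minimum → level 1) — the
  ROI's own range is split into `BN` bins, so any delineation change that
  alters the ROI minimum or maximum re-bins *every* pixel.

`texrepro` implements both rules, the texture machinery downstream of them
(GLCM, GLRLM, GLSZM, GLDM and NGTDM matrices; 69-feature and 57-feature
configurations; per-angle-average and √2-weighted-merge aggregation), the
reproducibility selection rule — two-way random-effects absolute-agreement
average-measures ICC > 0.8 on all three session pairs *and* Lin's CCC > 0.9
on the repeated-reader pair — and the comparison experiments: best-FBS vs
best-FBN by exact Fisher test, within-grid chi-square homogeneity, and
reproducible-feature counts as a function of segmentation overlap (Dice),
using a simulator of delineation variability (morphological openings /
closings plus elastic deformation, one retained mask per 0.05 Dice stratum
from 1.0 down to 0.65).

Because the underlying MRI datasets are not public, the package ships a
synthetic-study generator that emulates the reading design: 37 patients ×
2 regions × 6 sequences (444 ROIs per session), three reading sessions
whose masks are tuned to a mean inter-reader Dice of 0.84 and an
intra-reader Dice of 0.92, lesions with spatially correlated anisotropic
texture on sequence-specific intensity scales. It is aimed at radiomics
methodologists who want to probe discretization/reproducibility
interactions under controlled conditions.

## Worked example

```r
library(texrepro)

spec  <- dataset_spec(n_patients = 6, n_sequences = 2, seed = 101)
study <- generate_study(spec)
study
#> <synthetic_study> 24 ROIs x 3 sessions; mean inter-reader Dice 0.844, intra 0.914

experiment <- run_grid(study, schemes = c("fbs:5", "fbs:20", "fbn:64", "fbn:512"))
glance(experiment)[, c("sequence_name", "best_fbs", "best_fbn", "fisher_p")]
#> # A tibble: 2 x 4
#>   sequence_name best_fbs best_fbn fisher_p
#>   <chr>            <int>    <int>    <dbl>
#> 1 wDIXON-T2           32       17  0.0124
#> 2 ipDIXON-T2          28       13  0.00867
```

`best_fbs` / `best_fbn` are the highest numbers of reproducible features
(out of 69) over each method's settings for that sequence; `fisher_p` is
the two-sided exact test comparing those two proportions. The absolute
(FBS) method retains more reproducible features — the package's synthetic
studies reproduce the direction reported for clinical MR data. Per-setting
counts are in `tidy(experiment)`, the full coefficient table in
`experiment$report`, and `autoplot(experiment)` draws the comparison.

To trace reproducibility against delineation overlap:

```r
sims  <- simulate_study_rois(study, perturbation_config(n_candidates = 250, seed = 7))
curve <- dice_curve(study, sims, schemes = c("fbs:5", "fbs:20", "fbn:64", "fbn:512"))
autoplot(curve)   # counts fall as Dice drops; the FBS-FBN gap widens
```

See `vignettes/discretization-reproducibility.Rmd` for the model
assumptions, parameter meanings and numerical choices.

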