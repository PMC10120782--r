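---
title: "Quantifying the stromal microenvironment from H&E images and relating it to risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the stromal microenvironment from H&E images and relating it to risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smequant)
```

## The problem

The stromal microenvironment (SME) of a breast tumor — the connective-tissue
compartment with its resident lymphocytes, macrophages, fibroblasts and
endothelial cells — carries information about tumor biology that the
parenchymal markers (ER, PR, HER2, grade) do not. Two scalar phenotypes
summarize it on an ordinary H&E-stained section:

* **TSR**, the tumor-stroma ratio: `100 * stroma area / (tumor + stroma area)`,
  in percent of the fibroglandular tissue.
* **Ta-SCD**, the tumor-associated stromal cellular density: nucleated cells
  in the stroma per mm^2 of stroma (*standard* form). Multiplying the count by
  the average area of a single nucleus (2.0e-4 mm^2) before dividing by
  stromal area and scaling by 100 gives the *percent* form — the fraction of
  stromal area occupied by nuclei. Because the conversion constant is shared
  by every slide, the two forms are exactly proportional
  (`percent = standard * 0.02`), and their Pearson correlation across slides
  is analytically 1; the percent form is the analysis variable because it
  reads like an area fraction.

`smequant` implements the whole chain: a trainable tumor/stroma tissue
classifier, stroma-confined nucleated-cell detection, the two metrics, and
the epidemiological association engine that relates them to risk factors.
Because the patient images and data of the motivating study design are not
publicly deposited, the package ships *synthetic* slide and cohort
generators with exact ground truth; every stage is validated by parameter
recovery against that truth.

## The imaging pipeline

### Tissue classification

A random forest (100 trees, fixed seed) is trained on sparse point
annotations — by default 94 tumor and 67 stroma "datapoints", mirroring the
annotation budget of the classifier the design is based on (that classifier
is described as "160-datapoint" although the per-class counts sum to 161;
we expose both numbers and do not resolve the discrepancy). Each point
contributes a 13-dimensional feature vector of window statistics over a
32 um window: mean/SD of the RGB channels, mean/SD of the hematoxylin and
eosin optical-density channels from fixed Ruifrok-Johnston stain
deconvolution, mean/SD of the luminance gradient magnitude, and the
luminance entropy (16 bins). Window sums come from integral images, so a
single annotation point and a dense prediction grid run through identical
arithmetic.

Segmentation assigns background first (luminance above 0.9 of white — the
underlying study never states how non-tissue was removed, so this is our
choice), classifies the rest on a grid (default stride 4 px) and upsamples
by nearest neighbor. No smoothing is applied, which keeps the pixel
accounting exact: tumor + stroma + background + excluded pixel counts equal
the raster size, and areas are pixel counts times `mpp^2`. Whether the
original pipeline classified at full resolution is unknown; the stride is a
config knob, and a self-consistency test requires TSR at stride 1 and
stride 4 to agree within 2 percentage points.

### Stroma-confined cell detection

The detection channel is a blend `w * OD_hematoxylin + (1 - w) * OD_total`
(default `w = 0.8`); per-channel OD is `-log10((I + 1)/256)`. The named
knobs of the reference cell detector (size, shape, nuclear detection
weight, nuclear contrast threshold, optical density) are mirrored in
`detection_params()`; the actual values used by the commercial scripts are
not public, so defaults were tuned once on synthetic scenes with seeded
ground truth and then frozen:

* OD floor 0.6 — nuclei render around 0.8 on the detection channel, tumor
  texture stays below ~0.63, stroma matrix near 0.05;
* nuclear area gate 10-120 um^2, minimum circularity 0.4;
* contrast gate: candidate mean OD minus the mean OD of a 3-um annulus
  (foreground excluded) must exceed 0.05;
* watershed on the distance transform splits touching nuclei; the merge
  tolerance is `min_separation/8` in distance units (2 um separation by
  default), ties broken by raster order, so detection is deterministic;
* declumping: a candidate above 65 um^2 — larger than any plausible single
  nucleus — is treated as two fully fused nuclei and split along its major
  axis;
* epithelial-nest exclusion: connected dark regions larger than 300 um^2
  are infiltrating nests of malignant epithelium; every candidate whose
  centroid falls in one is discarded.

Analysis is confined to the stroma mask from the start: foreground touching
the tumor compartment would otherwise fuse with it and drag centroids of
boundary nuclei out of the stroma. One caveat discovered during validation:
the OD floor is *not* a monotone gate on counts in dense tissue, because a
higher floor erodes the bridge between touching nuclei and re-partitions
one component into two. The candidate gates (area, circularity, contrast)
are strictly monotone; tests assert floor-monotonicity only on isolated
nuclei where it genuinely holds.

## What the synthetic slides emulate — and what they do not

`generate_slide()` renders tumor as dark-purple, high-frequency blotch
texture and stroma as pink, low-frequency fiber texture on a white
background, with stromal nuclei as dark ellipses (radius 3.6 +/- 0.5 um,
clipped at +/-2 SD; axis ratio 0.6-1.0) placed by a homogeneous Poisson
point process over the stroma. Defaults are the study-scale conditions:
TSR near 75%, density 1550 cells/mm^2 (which converts to a percent Ta-SCD
near the cohort mean of ~31%), 1 um/px. Nest radii are rescaled until the
realized TSR is within 5 points of target; the exact realized value is the
ground truth. With `epithelial_nest_infiltration = TRUE`, packed micro-nests
of malignant nuclei are drawn inside the stroma; their pixels remain
*stroma* in the ground-truth mask — tissue compartments are defined at
tissue scale, and a tissue classifier cannot resolve a 20-cell nest — and
their cells are deliberately absent from `nuclei_centers`, which is exactly
what makes the nest-exclusion stage load-bearing.

The generator does **not** emulate staining physics, necrosis, fat or
vessels, scanner artifacts beyond a rectangular exclusion mask, or the
nuclear texture (chromatin) of real H&E. Passing recovery tests on these
scenes therefore demonstrates the *mechanics* of the pipeline — feature
learning from sparse points, area accounting, stain separation,
declumping, confinement — not performance on real slides, which would need
its own validation against pathologist annotations.

## The synthetic cohorts

`generate_cohort()` draws the covariate structure of a West-African breast
cancer case series: category marginals follow the published frequency
table (`gbhs_table1()`), e.g. 91% parous, 7% family history, 69.7%
grade 3. The three-hospital site split (45/35/20) is not tabulated in the
source and was chosen once as realistic. Parity is made age-dependent
(calibrated to keep the marginal at 91%), so age confounds parity-outcome
associations and adjustment is genuinely exercised. ER and PR are drawn
jointly (P(PR+|ER+) = 0.82, P(PR+|ER-) = 0.20), reproducing a realistic
~29% TNBC fraction; HER2 is independent at 24.5%.

Percent Ta-SCD is built as `intercept + sum(effects) + interactions +
N(0, sd)`, clipped to (5, 95) — the observed cohort range is roughly
11-59, so clipping is essentially inactive at the default sd of 7. Default
effect sizes sit at the scale of the published mutually adjusted
estimates (parous +2.92, FHBC +2.36, body size -1.02/-2.42, grade
+3.53/+5.22; TSR responds to grade at -2.07/-9.19 and to nothing else).
Tumor variables are masked missing-at-random — the missingness probability
depends on observed site and age only, scaled to hit the published unknown
rates (ER 25.0%, PR 25.4%, HER2 29.4%, grade 14.1%, size 4.8%) — matching
the assumption under which chained-equations imputation is valid. MNAR
mechanisms are out of scope.

## The association engine

* `kruskal_wallis()` — ties-corrected H against chi-square; when every
  value is tied the statistic is defined as 0 (the ties correction is
  degenerate there).
* `fit_linear()` — OLS with treatment coding. *Partial* adjustment: the
  exposure plus age, site, tissue area; *mutual*: plus the other risk
  factors (menarche, parity, body size, family history by default). Age
  enters as its 4-level category to match the reporting convention;
  continuous age is a switch. Tissue area enters untransformed (no
  transform is stated in the design). "n/a" and unknown categories are
  dropped from complete-case fits; imputation is the primary missing-data
  path.
* `trend_test()` — consecutive integer scores (0, 1, 2, ...) over ordered
  categories; custom scores (e.g. category medians) can be supplied. The
  design reports p-trend without stating its scores; integers are the
  conventional default.
* `heterogeneity_test()` — exposure-by-modifier product terms tested
  jointly by a Wald chi-square (the design reports one p-heterogeneity per
  modifier without naming the test); stratum-specific effects come from
  linear combinations of main and product terms.
* `mice_impute()` — chained equations over the incomplete tumor variables:
  logistic draws for binary, multinomial for three-level variables, 10
  sweeps per imputation, m = 5 by default. Each conditional model is fit
  on a bootstrap resample of the observed rows so that parameter
  uncertainty propagates into between-imputation variance (approximately
  proper imputation). Observed values are never altered.
* `rubin_pool()` — pooled beta is the mean; `W = mean(se^2)`,
  `B = var(beta)`, `T = W + (1 + 1/m) B`; degrees of freedom by the
  Barnard-Rubin small-sample formula, reducing to the complete-data df
  when B = 0. The identity `T = W + (1 + 1/m) B` is asserted on every
  pooled term.

All p-values are two-sided; 0.05 is the significance convention.

## Numerical and design choices worth knowing

* Coordinates are 0-based in files, 1-based in R (row, col); areas are
  always `pixels * mpp^2 / 1e6` mm^2.
* The background-luminance threshold (0.9), the 32-um feature window, the
  forest size (100), and the stride (4) are frozen config defaults, not
  fitted quantities.
* The nucleus-area constant 2.0e-4 mm^2 is treated as a fixed conversion
  constant of unknown provenance; it is a parameter of `compute_tascd()`.
* Whether final cellularity should distinguish intra- from peri-tumoral
  stroma is left open by the metric definition, which pools all stroma;
  the pooled interpretation is implemented.
* Degenerate inputs fail loudly: zero tissue area (TSR), zero stroma area
  (Ta-SCD, detection), single-class annotations, collinear designs,
  single-level modifiers, 100%-missing variables, unreachable target TSR.

## Problem sizes used in validation

The test suite and the acceptance script run at desk scale, chosen once:
scenes of 192-512 px at 1 um/px (0.04-0.26 mm^2 of tissue, 140-900 nuclei),
20-scene segmentation/count recovery, 30 counting regions of 500 x 500 um^2
spanning 500-4000 cells/mm^2, cohorts of n = 2000 with 200-seed coverage
loops, and 1500-2000 replicates for type-I-error checks. At these sizes the
suite demonstrates: Dice >= 0.85 per tissue class end to end, stromal
counts within +/-10% of seeded truth (the residual ~5% negative bias is
fused nuclei that declumping cannot see), automated-vs-truth count
correlation >= 0.9, ~95% coverage of an injected parity effect through the
MICE + Rubin path, and type-I error within [0.035, 0.065] for the
Kruskal-Wallis and heterogeneity tests.

## Known limitations

* Synthetic textures are far easier to classify than real H&E; the
  out-of-bag accuracy (~0.99) and Dice (~0.96-0.99) here say nothing about
  accuracy on real slides.
* Fully fused nucleus pairs are intrinsically ambiguous to a shape-based
  detector; counts carry a small negative bias at high density.
* The imputation engine covers the five tumor variables with categorical
  conditional models; continuous-variable imputation (predictive mean
  matching etc.) is not implemented because the design needs none.
* No survival/prognostic modeling and no case-control risk analysis — the
  engine relates risk factors to SME phenotypes among cases only.
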