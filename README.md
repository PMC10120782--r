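# smequant

Quantification of the tumor **stromal microenvironment** (SME) on
H&E-stained histology images, and an epidemiological engine for relating
the resulting phenotypes to breast-cancer risk factors.

The SME — the connective-tissue compartment of a tumor and its resident
nucleated cells (lymphocytes, macrophages, fibroblasts, endothelial
cells) — is summarized by two scalar phenotypes per slide:

* **TSR** (tumor-stroma ratio, %):
  `TSR = 100 × stroma area / (tumor area + stroma area)`
* **Ta-SCD** (tumor-associated stromal cellular density):
  `standard = n_cells / stroma area (mm²)`, and as a percent of stromal
  area occupied by nuclei, `percent = n_cells × 2.0·10⁻⁴ mm² / stroma area
  × 100`. The two forms are exactly proportional (percent = 0.02 ×
  standard), so their correlation across slides is analytically 1.

The pipeline has four imaging stages and one statistics stage:

1. **Tissue classification** — a random forest trained on sparse point
   annotations (default 94 tumor + 67 stroma "datapoints") over
   13-dimensional patch features (RGB and hematoxylin/eosin
   optical-density window statistics, gradient, entropy); whole-slide
   segmentation on a grid with exact pixel-area accounting in mm².
2. **Stroma-confined cell detection** — stain deconvolution
   (Ruifrok–Johnston vectors), OD thresholding, distance-transform
   watershed with declumping, size/shape/contrast gating, and exclusion of
   infiltrating epithelial nests (connected dark regions too large to be
   single nuclei).
3. **Metrics** — TSR and Ta-SCD per slide.
4. **Synthetic generators** — H&E-like slides with exact ground-truth
   masks and seeded nuclei, and patient cohorts with realistic covariate
   marginals, injectable effects and missing-at-random tumor markers, so
   every stage is testable by parameter recovery.
5. **Association engine** — Kruskal–Wallis comparisons, partially and
   mutually adjusted linear models, ordinal trend tests, multiplicative
   interaction (heterogeneity) tests, and multiple imputation by chained
   equations (m = 5) with Rubin's-rules pooling
   (`T = W + (1 + 1/m)·B`, Barnard–Rubin degrees of freedom).

## Worked example

```r
library(smequant)

# a synthetic slide with known ground truth
scene <- generate_slide(scene_params(seed = 3))

# train the tissue classifier on sparse annotations and segment
ann   <- sample_annotation_points(scene$ground_truth, seed = 2)
model <- train_tissue_classifier(scene$slide, ann)
model
#> <tissue_model> 100 trees, 94 tumor + 67 stroma training points, OOB accuracy 0.994

seg <- segment_slide(model, scene$slide)
seg
#> <tissue_segmentation 'synth-3'> tumor 0.034 mm^2, stroma 0.095 mm^2
segmentation_dice(seg, scene$ground_truth)
#> # A tibble: 2 × 2
#>   class   dice
#> 1 tumor  0.960
#> 2 stroma 0.985

# detect nucleated cells confined to the stroma, compute the metrics
det <- detect_stromal_cells(scene$slide, seg)
sme_metrics(seg, det)[, 1:4]
#> # A tibble: 1 × 4
#>   slide_id tsr_percent tascd_standard tascd_percent
#> 1 synth-3         73.7          1360.          27.2
```

The segmentation recovered the true TSR (73.2%) within half a point, and
the detected density (1360 cells/mm²) sits close to the seeded truth
(138 nuclei in 0.095 mm² ≈ 1450/mm²); the percent Ta-SCD is exactly
0.02 × the standard form.

On the cohort side:

```r
coh  <- generate_cohort(2000, effect_spec(), seed = 5)   # parous effect +2.92 injected
imp  <- mice_impute(coh, m = 5, seed = 9)                # impute ER/PR/HER2, grade, size
spec <- model_spec("tascd_percent", "parity", "mutual")
fit  <- fit_pooled(imp, spec)
make_report(fit)
#> # A tibble: 2 × 5
#>   exposure level       estimate           p_value
#> 1 parity   nulliparous 1.00 (reference)     NA
#> 2 parity   parous      2.28 (1.07, 3.49)    2.33e-4
```

The pooled mutually-adjusted estimate covers the injected effect; across
200 simulated cohorts the 95% CI covers it ~95–96% of the time (this is
one of the acceptance checks).

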