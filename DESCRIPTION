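Package: smequant
Title: Quantification of the Tumor Stromal Microenvironment from H&E Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying stromal-microenvironment
    phenotypes on hematoxylin-and-eosin histology images and relating them to
    epidemiological risk factors. Provides a random-forest tumor/stroma tissue
    classifier trained from sparse point annotations, stroma-confined nucleated
    cell detection via stain deconvolution with epithelial-nest exclusion, the
    tumor-stroma ratio (TSR) and tumor-associated stromal cellular density
    (Ta-SCD) metrics, synthetic slide and cohort generators with exact ground
    truth for validation, and an association engine covering Kruskal-Wallis
    comparisons, partially and mutually adjusted linear models, trend and
    heterogeneity tests, and multiple imputation by chained equations with
    Rubin's-rules pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    EBImage,
    ranger,
    nnet,
    yaml,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
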