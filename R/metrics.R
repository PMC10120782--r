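#' Single-nucleus area constant (mm^2)
#'
#' Average area of a single nucleus used to convert the standard Ta-SCD
#' (cells per mm^2 of stroma) into a percent of stromal area occupied by
#' nuclei. Treated as a fixed conversion constant; configurable in
#' [compute_tascd()].
#' @export
NUCLEUS_AREA_MM2 <- 2.0e-4

#' Tumor-stroma ratio (percent)
#'
#' `100 * stroma_area / (tumor_area + stroma_area)`: the percent of the
#' fibroglandular tissue area (tumor + stroma; background and excluded
#' pixels contribute nothing) that is stroma.
#'
#' @param x a `tissue_segmentation`, a `slide_ground_truth`, or the stroma
#'   area in mm^2 (with `tumor_area_mm2` supplied)
#' @param ... passed to methods
#' @return TSR in percent
#' @export
compute_tsr <- function(x, ...) UseMethod("compute_tsr")

#' @rdname compute_tsr
#' @param tumor_area_mm2 tumor area when `x` is the stroma area
#' @export
compute_tsr.numeric <- function(x, tumor_area_mm2, ...) {
  tissue <- x + tumor_area_mm2
  if (any(tissue <= 0)) {
    stop("zero tissue area: TSR is undefined (slide fails QC)", call. = FALSE)
  }
  100 * x / tissue
}

#' @export
compute_tsr.tissue_segmentation <- function(x, ...) {
  compute_tsr(x$stroma_area_mm2, x$tumor_area_mm2)
}

#' @export
compute_tsr.slide_ground_truth <- function(x, ...) {
  # from mask pixel counts, the same expression the generator stores, so
  # the oracle identity is exact to the last bit
  s <- sum(x$tissue_mask == LBL_STROMA)
  t <- sum(x$tissue_mask == LBL_TUMOR)
  if (s + t == 0) {
    stop("zero tissue area: TSR is undefined (slide fails QC)", call. = FALSE)
  }
  100 * s / (s + t)
}

#' Tumor-associated stromal cellular density (Ta-SCD)
#'
#' Standard form: nucleated cells in the stroma divided by stromal area
#' (cells/mm^2). Percent form: the same count times the average area of a
#' single nucleus (`nucleus_area_mm2`, default 2.0e-4 mm^2), divided by
#' stromal area, times 100 -- i.e. the percent of stromal area occupied by
#' nuclei. With a shared constant the two are exactly proportional
#' (`percent = standard * nucleus_area_mm2 * 100`).
#'
#' @param n_cells nucleated cell count(s) in the stroma
#' @param stroma_area_mm2 stromal area(s) in mm^2 (> 0)
#' @param nucleus_area_mm2 single-nucleus area constant
#' @return tibble (`tascd_standard`, `tascd_percent`)
#' @export
compute_tascd <- function(n_cells, stroma_area_mm2,
                          nucleus_area_mm2 = NUCLEUS_AREA_MM2) {
  stopifnot(all(n_cells >= 0))
  if (any(stroma_area_mm2 <= 0)) {
    stop("zero stroma area: Ta-SCD is undefined (slide fails QC)",
         call. = FALSE)
  }
  standard <- n_cells / stroma_area_mm2
  tibble::tibble(tascd_standard = standard,
                 tascd_percent = standard * nucleus_area_mm2 * 100)
}

#' Per-slide stromal-microenvironment metrics
#'
#' Combines a segmentation and a detection into the two SME phenotypes:
#' TSR (%) and Ta-SCD (standard and percent). The percent Ta-SCD is the
#' analysis variable downstream; the standard form is retained for audit.
#'
#' @param seg a `tissue_segmentation`
#' @param detection the matching `stromal_cell_detection`
#' @param nucleus_area_mm2 single-nucleus area constant
#' @return one-row tibble (`slide_id`, `tsr_percent`, `tascd_standard`,
#'   `tascd_percent`, areas, `n_cells`, `nucleus_area_mm2`)
#' @export
sme_metrics <- function(seg, detection, nucleus_area_mm2 = NUCLEUS_AREA_MM2) {
  stopifnot(inherits(seg, "tissue_segmentation"),
            inherits(detection, "stromal_cell_detection"),
            identical(seg$slide_id, detection$slide_id))
  ta <- compute_tascd(detection$n_cells, detection$stroma_area_mm2,
                      nucleus_area_mm2)
  tibble::tibble(
    slide_id = seg$slide_id,
    tsr_percent = compute_tsr(seg),
    tascd_standard = ta$tascd_standard,
    tascd_percent = ta$tascd_percent,
    tumor_area_mm2 = seg$tumor_area_mm2,
    stroma_area_mm2 = seg$stroma_area_mm2,
    tissue_area_mm2 = seg$tissue_area_mm2,
    n_cells = detection$n_cells,
    nucleus_area_mm2 = nucleus_area_mm2
  )
}

#' Correlation between standard and percent Ta-SCD across slides
#'
#' With a shared nucleus-area constant the two forms are exactly linearly
#' related, so the Pearson correlation is analytically 1; the function
#' computes it from the data as a pipeline audit, and warns when per-slide
#' constants differ (in which case r may drop below 1).
#'
#' @param metrics tibble of per-slide metrics from [sme_metrics()]
#' @return tibble (`r`, `n`, `shared_constant`)
#' @export
percent_standard_correlation <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("tascd_standard", "tascd_percent") %in% names(metrics)))
  if (nrow(metrics) < 3L) {
    stop("at least 3 slides are required", call. = FALSE)
  }
  shared <- !("nucleus_area_mm2" %in% names(metrics)) ||
    length(unique(metrics$nucleus_area_mm2)) == 1L
  if (!shared) {
    warning("per-slide nucleus-area constants differ; the standard/percent ",
            "relation is no longer exactly linear")
  }
  if (stats::sd(metrics$tascd_standard) == 0 ||
      stats::sd(metrics$tascd_percent) == 0) {
    warning("zero variance across slides; correlation is undefined")
    return(tibble::tibble(r = NA_real_, n = nrow(metrics),
                          shared_constant = shared))
  }
  tibble::tibble(r = stats::cor(metrics$tascd_standard, metrics$tascd_percent),
                 n = nrow(metrics), shared_constant = shared)
}
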