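#' Train the random-forest tumor/stroma tissue classifier
#'
#' Fits a random forest on patch features extracted at sparse annotation
#' points (the "datapoints" a pathologist clicks), exactly one feature
#' vector per point. Out-of-bag accuracy is reported with the model.
#'
#' @param slides an `sme_slide` or a list of them (matched to annotations
#'   by `slide_id`)
#' @param annotations tibble (`slide_id`, `row`, `col`, `class`) with
#'   classes `tumor` / `stroma`; see [sample_annotation_points()]
#' @param config a [tissue_config()]
#' @return a `tissue_model` with the fitted forest, its configuration, and
#'   `oob_accuracy`
#' @export
train_tissue_classifier <- function(slides, annotations,
                                    config = tissue_config()) {
  slides <- as_slide_list(slides)
  stopifnot(is.data.frame(annotations),
            all(c("slide_id", "row", "col", "class") %in% names(annotations)))
  classes <- unique(annotations$class)
  if (!all(classes %in% c("tumor", "stroma"))) {
    stop("annotation classes must be 'tumor' or 'stroma'", call. = FALSE)
  }
  if (length(classes) < 2L) {
    stop("annotations contain a single class ('", classes,
         "'); both tumor and stroma points are required", call. = FALSE)
  }
  feats <- lapply(split(annotations, annotations$slide_id), function(ann) {
    sl <- slides[[ann$slide_id[1]]]
    if (is.null(sl)) stop("no slide with id '", ann$slide_id[1], "'", call. = FALSE)
    extract_features(sl, ann$row, ann$col,
                     window_px = window_px_for(sl, config$window_um))
  })
  x <- do.call(rbind, feats)
  y <- factor(unlist(lapply(split(annotations, annotations$slide_id),
                            function(a) a$class), use.names = FALSE),
              levels = c("tumor", "stroma"))
  df <- data.frame(x, class = y)
  fit <- ranger::ranger(class ~ ., data = df,
                        num.trees = config$n_trees,
                        seed = config$seed,
                        probability = FALSE)
  structure(
    list(forest = fit, config = config, feature_names = feature_names(),
         classes = levels(y), n_points = table(y),
         oob_accuracy = 1 - fit$prediction.error),
    class = "tissue_model"
  )
}

as_slide_list <- function(slides) {
  if (inherits(slides, "sme_slide")) slides <- list(slides)
  stopifnot(is.list(slides), all(vapply(slides, inherits, TRUE, "sme_slide")))
  stats::setNames(slides, vapply(slides, `[[`, "", "slide_id"))
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %d trees, %s training points, OOB accuracy %.3f\n",
              x$config$n_trees,
              paste(sprintf("%d %s", x$n_points, names(x$n_points)),
                    collapse = " + "),
              x$oob_accuracy))
  invisible(x)
}

#' Segment a slide into background / tumor / stroma / excluded
#'
#' Background is assigned first by a luminance threshold; the remaining
#' pixels are classified on a regular grid of `stride_px` and upsampled to
#' full resolution by nearest neighbor (no smoothing, so the area
#' accounting is exact); the slide's exclusion mask is applied last.
#' Per-class areas are pixel counts times `mpp^2`.
#'
#' @param model a `tissue_model`
#' @param slide an `sme_slide` with a valid mpp
#' @param stride_px classification grid stride (1 = every pixel)
#' @return a `tissue_segmentation`: `label_raster` (0 = background,
#'   1 = tumor, 2 = stroma, 3 = excluded), per-class areas in mm^2 and
#'   `tissue_area_mm2 = tumor + stroma`
#' @export
segment_slide <- function(model, slide, stride_px = NULL) {
  stopifnot(inherits(model, "tissue_model"), inherits(slide, "sme_slide"))
  if (is.na(slide$mpp)) {
    stop("slide '", slide$slide_id,
         "' has no mpp; areas in mm^2 would be meaningless", call. = FALSE)
  }
  stride <- as.integer(stride_px %||% model$config$stride_px)
  d <- slide_dim(slide)
  gray <- slide_gray(slide)
  background <- gray >= model$config$background_luminance

  labels <- matrix(LBL_BACKGROUND, d[1], d[2])
  fg <- !background
  if (any(fg)) {
    grid_r <- seq(1L, d[1], by = stride)
    grid_c <- seq(1L, d[2], by = stride)
    pts <- expand.grid(row = grid_r, col = grid_c)
    tabs <- feature_tables(slide, window_px_for(slide, model$config$window_um))
    x <- features_at(tabs, pts$row, pts$col)
    pred <- stats::predict(model$forest, data = data.frame(x),
                           seed = model$config$seed)$predictions
    lab_grid <- matrix(ifelse(pred == "tumor", LBL_TUMOR, LBL_STROMA),
                       length(grid_r), length(grid_c))
    # nearest grid point per pixel
    map_r <- pmin(round((seq_len(d[1]) - 1L) / stride) + 1L, length(grid_r))
    map_c <- pmin(round((seq_len(d[2]) - 1L) / stride) + 1L, length(grid_c))
    full <- lab_grid[map_r, map_c]
    labels[fg] <- full[fg]
  }
  if (!is.null(slide$excluded_mask)) labels[slide$excluded_mask] <- LBL_EXCLUDED

  tumor_area <- px_to_mm2(sum(labels == LBL_TUMOR), slide$mpp)
  stroma_area <- px_to_mm2(sum(labels == LBL_STROMA), slide$mpp)
  structure(
    list(slide_id = slide$slide_id,
         label_raster = labels,
         tumor_area_mm2 = tumor_area,
         stroma_area_mm2 = stroma_area,
         tissue_area_mm2 = tumor_area + stroma_area,
         mpp = slide$mpp, stride_px = stride),
    class = "tissue_segmentation"
  )
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat(sprintf("<tissue_segmentation '%s'> tumor %.3f mm^2, stroma %.3f mm^2\n",
              x$slide_id, x$tumor_area_mm2, x$stroma_area_mm2))
  invisible(x)
}

#' Build a segmentation directly from a ground-truth mask
#'
#' Useful for validating downstream stages against exact tissue labels.
#'
#' @param gt a `slide_ground_truth`
#' @return a `tissue_segmentation` whose raster is the true mask
#' @export
segmentation_from_truth <- function(gt) {
  stopifnot(inherits(gt, "slide_ground_truth"))
  structure(
    list(slide_id = gt$slide_id,
         label_raster = gt$tissue_mask,
         tumor_area_mm2 = gt$tumor_area_mm2,
         stroma_area_mm2 = gt$stroma_area_mm2,
         tissue_area_mm2 = gt$tumor_area_mm2 + gt$stroma_area_mm2,
         mpp = gt$mpp, stride_px = 1L),
    class = "tissue_segmentation"
  )
}

#' Dice coefficient between a segmentation and ground truth, per class
#'
#' @param seg a `tissue_segmentation`
#' @param gt a `slide_ground_truth` for the same slide
#' @return tibble (`class`, `dice`)
#' @export
segmentation_dice <- function(seg, gt) {
  stopifnot(all(dim(seg$label_raster) == dim(gt$tissue_mask)))
  codes <- c(tumor = LBL_TUMOR, stroma = LBL_STROMA)
  tibble::tibble(
    class = names(codes),
    dice = vapply(codes, function(code) {
      a <- seg$label_raster == code
      b <- gt$tissue_mask == code
      denom <- sum(a) + sum(b)
      if (denom == 0) return(NA_real_)
      2 * sum(a & b) / denom
    }, numeric(1))
  )
}

#' Concordance of two independently trained classifiers
#'
#' Segments each slide with both models and reports Spearman's rho between
#' the per-slide tumor areas and between the per-slide stroma areas --
#' the same design used to show inter-pathologist reproducibility of the
#' original classifier.
#'
#' @param model_a,model_b `tissue_model`s trained on independently sampled
#'   annotation sets
#' @param slides list of `sme_slide`s (at least 3)
#' @param stride_px grid stride passed to [segment_slide()]
#' @return tibble (`class`, `rho`, `n_slides`); `rho` is `NA` when a class
#'   has zero area variance across slides
#' @export
reproducibility_check <- function(model_a, model_b, slides, stride_px = NULL) {
  slides <- as_slide_list(slides)
  if (length(slides) < 3L) {
    stop("at least 3 slides are required for a stable rank correlation",
         call. = FALSE)
  }
  areas <- purrr::map_dfr(slides, function(sl) {
    sa <- segment_slide(model_a, sl, stride_px)
    sb <- segment_slide(model_b, sl, stride_px)
    tibble::tibble(slide_id = sl$slide_id,
                   tumor_a = sa$tumor_area_mm2, tumor_b = sb$tumor_area_mm2,
                   stroma_a = sa$stroma_area_mm2, stroma_b = sb$stroma_area_mm2)
  })
  safe_rho <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  tibble::tibble(
    class = c("tumor", "stroma"),
    rho = c(safe_rho(areas$tumor_a, areas$tumor_b),
            safe_rho(areas$stroma_a, areas$stroma_b)),
    n_slides = length(slides)
  )
}
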