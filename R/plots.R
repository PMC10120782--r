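# ggplot2 views of the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

slide_raster_df <- function(img) {
  d <- dim(img)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    fill = grDevices::rgb(img[, , 1], img[, , 2], img[, , 3],
                          maxColorValue = 255)
  )
}

#' @method autoplot sme_slide
#' @export
autoplot.sme_slide <- function(object, ...) {
  df <- slide_raster_df(object$image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$slide_id,
                  x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' @method autoplot tissue_segmentation
#' @export
autoplot.tissue_segmentation <- function(object, ...) {
  lab <- object$label_raster
  d <- dim(lab)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    class = factor(c("background", "tumor", "stroma", "excluded")[lab + 1L],
                   levels = c("background", "tumor", "stroma", "excluded"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(background = "white",
                                          tumor = "#c23b22",
                                          stroma = "#3cb371",
                                          excluded = "grey40")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s: tumor %.2f mm2, stroma %.2f mm2",
                                  object$slide_id, object$tumor_area_mm2,
                                  object$stroma_area_mm2),
                  x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' @method autoplot stromal_cell_detection
#' @export
autoplot.stromal_cell_detection <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$area_um2),
                        color = "#2b2d77", alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s: %d stromal cells (%.0f /mm2)",
                                  object$slide_id, object$n_cells,
                                  object$n_cells / object$stroma_area_mm2),
                  x = "column (px)", y = "row (px)",
                  size = "area (um2)") +
    ggplot2::theme_minimal()
}

#' Forest plot of pooled regression coefficients
#'
#' @param x an `sme_pooled_fit` or pooled/term tibble with `level`, `beta`,
#'   `ci_low`, `ci_high`
#' @return a ggplot
#' @export
plot_forest <- function(x) {
  df <- if (inherits(x, "sme_pooled_fit")) x$terms else tibble::as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                   y = paste(.data$term, .data$level))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "beta (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot sme_pooled_fit
#' @export
autoplot.sme_pooled_fit <- function(object, ...) plot_forest(object)
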