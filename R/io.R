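# Plain-text interchange: CSV for point/area tables, YAML for parameter
# sets, and a minimal GeoJSON point dialect for annotations.

#' Write / read annotation points as CSV
#'
#' Columns: `slide_id`, `row`, `col`, `class`.
#'
#' @param annotations annotation tibble
#' @param path CSV path
#' @return `path` (write) or the annotation tibble (read)
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read annotation points as GeoJSON
#'
#' A minimal point dialect: a `FeatureCollection` of `Point` features with
#' `coordinates = [col, row]` (x, y) and properties `slide_id`, `class`.
#'
#' @param annotations annotation tibble
#' @param path `.geojson` path
#' @return `path` (write) or the annotation tibble (read)
#' @export
write_annotations_geojson <- function(annotations, path) {
  features <- purrr::pmap(annotations, function(slide_id, row, col, class, ...) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(col, row)),
         properties = list(slide_id = slide_id, class = class))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations_geojson
#' @export
read_annotations_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  purrr::map_dfr(gj$features, function(f) {
    tibble::tibble(slide_id = f$properties$slide_id,
                   row = f$geometry$coordinates[[2]],
                   col = f$geometry$coordinates[[1]],
                   class = f$properties$class)
  })
}

#' Write detected cells and the per-slide summary as CSV
#'
#' @param detection a `stromal_cell_detection`
#' @param cells_path per-cell CSV (`slide_id`, `row`, `col`, `area_um2`,
#'   `circularity`, `mean_od`)
#' @param summary_path optional per-slide summary CSV (`slide_id`,
#'   `n_cells`, `stroma_area_mm2`)
#' @return `cells_path`, invisibly
#' @export
write_detection_csv <- function(detection, cells_path, summary_path = NULL) {
  utils::write.csv(tidy(detection), cells_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.csv(glance(detection), summary_path, row.names = FALSE)
  }
  invisible(cells_path)
}

#' Write / read scene or detection parameters as YAML
#'
#' @param params a [scene_params()] or [detection_params()] list
#' @param path YAML path
#' @return `path` (write) or a parameter list (read); the stored `kind`
#'   field restores the class on read
#' @export
write_params_yaml <- function(params, path) {
  kind <- class(params)[1]
  x <- unclass(params)
  if (!is.null(x$stain_vectors)) x$stain_vectors <- as.vector(t(x$stain_vectors))
  yaml::write_yaml(c(list(kind = kind), x), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  kind <- x$kind; x$kind <- NULL
  if (!is.null(x$stain_vectors)) {
    x$stain_vectors <- matrix(unlist(x$stain_vectors), 3, 3, byrow = TRUE,
                              dimnames = list(rownames(HE_STAIN_VECTORS), NULL))
  }
  num_vec <- c("nest_radius_um", "nucleus_radius_um")
  for (v in num_vec) if (!is.null(x[[v]])) x[[v]] <- unlist(x[[v]])
  do.call(kind, x)
}

#' Write slide ground truth to plain files
#'
#' The tissue mask goes to a single-channel label image (0 = background,
#' 1 = tumor, 2 = stroma) and the seeded nuclei centers to a CSV
#' (`slide_id`, `row`, `col`).
#'
#' @param gt a `slide_ground_truth`
#' @param mask_path label image path (`.tif`/`.png`)
#' @param centers_path nuclei-centers CSV path
#' @return `mask_path`, invisibly
#' @export
write_ground_truth <- function(gt, mask_path, centers_path) {
  write_label_raster(gt$tissue_mask, mask_path)
  utils::write.csv(
    dplyr::mutate(gt$nuclei_centers, slide_id = gt$slide_id, .before = 1),
    centers_path, row.names = FALSE)
  invisible(mask_path)
}

#' Write a cohort table as CSV
#'
#' @param cohort cohort tibble from [generate_cohort()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV, restoring the factor coding
#'
#' @param path CSV path written by [write_cohort_csv()]
#' @return cohort tibble with the documented factor levels
#' @export
read_cohort_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                          check.names = FALSE))
  lv <- cohort_levels()
  ords <- ordinal_variables()
  for (v in intersect(names(lv), names(df))) {
    df[[v]] <- factor(df[[v]], levels = lv[[v]], ordered = v %in% ords)
  }
  df
}
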