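#' Parameters of the stromal cell detector
#'
#' Mirrors the knobs of a morphometric nucleus detector: size and shape
#' gates, the hematoxylin-vs-total mixing weight of the detection channel,
#' a local contrast gate, an optical-density floor, and the connected-dark-
#' region area above which a region is treated as an infiltrating
#' epithelial nest and all its nuclei discarded. Defaults were fixed once
#' against synthetic scenes with seeded ground truth.
#'
#' @param min_nuclear_area_um2,max_nuclear_area_um2 nucleus area gate
#' @param min_circularity minimum `4*pi*area / perimeter^2`
#' @param nuclear_detection_weight weight of the hematoxylin OD channel in
#'   the detection channel (`w * OD_hematoxylin + (1 - w) * OD_total`)
#' @param nuclear_contrast_threshold minimum candidate-minus-annulus mean
#'   OD (annulus of `annulus_um` around the candidate, foreground excluded)
#' @param min_optical_density detection-channel threshold for foreground
#' @param nest_area_threshold_um2 connected dark regions larger than this
#'   are epithelial nests; `Inf` disables nest exclusion
#' @param annulus_um width of the local-background annulus
#' @param min_separation_um minimum separation of watershed seeds when
#'   splitting touching nuclei
#' @param declump_area_um2 candidates larger than this (but still within
#'   `max_nuclear_area_um2`) are taken to be two fully fused nuclei that
#'   the watershed could not separate and are split along their major
#'   axis; `Inf` disables declumping
#' @param stain_vectors 3 x 3 stain matrix (rows = hematoxylin, eosin,
#'   residual), defaults to the Ruifrok-Johnston H&E basis
#' @return a `detection_params` list
#' @export
detection_params <- function(min_nuclear_area_um2 = 10,
                             max_nuclear_area_um2 = 120,
                             min_circularity = 0.4,
                             nuclear_detection_weight = 0.8,
                             nuclear_contrast_threshold = 0.05,
                             min_optical_density = 0.6,
                             nest_area_threshold_um2 = 300,
                             annulus_um = 3,
                             min_separation_um = 2,
                             declump_area_um2 = 65,
                             stain_vectors = HE_STAIN_VECTORS) {
  stopifnot(min_nuclear_area_um2 > 0,
            min_nuclear_area_um2 < max_nuclear_area_um2,
            min_circularity >= 0, min_circularity <= 1,
            is.finite(min_optical_density))
  structure(list(min_nuclear_area_um2 = min_nuclear_area_um2,
                 max_nuclear_area_um2 = max_nuclear_area_um2,
                 min_circularity = min_circularity,
                 nuclear_detection_weight = nuclear_detection_weight,
                 nuclear_contrast_threshold = nuclear_contrast_threshold,
                 min_optical_density = min_optical_density,
                 nest_area_threshold_um2 = nest_area_threshold_um2,
                 annulus_um = annulus_um,
                 min_separation_um = min_separation_um,
                 declump_area_um2 = declump_area_um2,
                 stain_vectors = stain_vectors),
            class = "detection_params")
}

#' Detection-channel optical density map
#'
#' Per-channel OD is `-log10((I + 1) / 256)`. The detection channel blends
#' the hematoxylin concentration from fixed stain-vector color
#' deconvolution with the total (mean RGB) OD:
#' `w * OD_H + (1 - w) * OD_total`, clamped at zero.
#'
#' @param slide an `sme_slide`
#' @param params a [detection_params()]
#' @return non-negative numeric matrix (H x W)
#' @export
optical_density_map <- function(slide, params = detection_params()) {
  stains <- stain_od_maps(slide$image, params$stain_vectors)
  w <- params$nuclear_detection_weight
  pmax(w * stains$h + (1 - w) * stains$total, 0)
}

# split a pixel component in two along its major axis; returns the two
# half centroids as integer (row, col) pairs
split_component <- function(ix, nr) {
  rs <- ((ix - 1L) %% nr) + 1L
  cs <- ((ix - 1L) %/% nr) + 1L
  xy <- cbind(rs, cs)
  ctr <- colMeans(xy)
  cxy <- sweep(xy, 2L, ctr)
  ev <- eigen(stats::cov(cxy), symmetric = TRUE)$vectors[, 1]
  proj <- cxy %*% ev
  side <- proj > stats::median(proj)
  if (!any(side) || all(side)) side <- proj > 0
  if (!any(side) || all(side)) side <- seq_along(ix) > length(ix) / 2
  h1 <- round(colMeans(xy[!side, , drop = FALSE]))
  h2 <- round(colMeans(xy[side, , drop = FALSE]))
  list(row = as.integer(c(h1[1], h2[1])), col = as.integer(c(h1[2], h2[2])))
}

# label connected foreground regions; returns an integer matrix
label_regions <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
}

#' Detect nucleated cells confined to the stroma
#'
#' Pipeline: threshold the detection-channel OD at `min_optical_density`;
#' split touching nuclei by distance-transform watershed (seeds separated
#' by at least `min_separation_um`, ties broken by raster order); keep
#' components within the area and circularity gates whose local contrast
#' (candidate mean OD minus annulus mean OD) clears
#' `nuclear_contrast_threshold`; keep centroids lying on stroma-labeled,
#' non-excluded pixels; finally drop members of epithelial nests
#' ([exclude_epithelial_nests()]). Fully deterministic.
#'
#' @param slide an `sme_slide`
#' @param seg the slide's `tissue_segmentation`
#' @param params a [detection_params()]
#' @return a `stromal_cell_detection`: tibble of cells (`row`, `col`,
#'   `area_um2`, `circularity`, `mean_od`), `n_cells`, `stroma_area_mm2`
#' @export
detect_stromal_cells <- function(slide, seg, params = detection_params()) {
  stopifnot(inherits(slide, "sme_slide"), inherits(seg, "tissue_segmentation"))
  if (!identical(dim(seg$label_raster), slide_dim(slide))) {
    stop("segmentation does not match the slide dimensions", call. = FALSE)
  }
  if (seg$stroma_area_mm2 <= 0) {
    stop("segmentation has zero stroma area; slide fails QC for cell ",
         "detection", call. = FALSE)
  }
  mpp <- slide$mpp
  od <- optical_density_map(slide, params)
  stroma <- seg$label_raster == LBL_STROMA
  # confine analysis to the stromal compartment up front: foreground
  # touching the tumor mask would otherwise fuse with it and drag
  # centroids of boundary nuclei out of the stroma
  od_stroma <- od
  od_stroma[!stroma] <- 0
  fg <- od_stroma >= params$min_optical_density
  if (!is.null(slide$excluded_mask)) fg[slide$excluded_mask] <- FALSE

  cells <- tibble::tibble(row = integer(), col = integer(),
                          area_um2 = numeric(), circularity = numeric(),
                          mean_od = numeric())
  if (any(fg)) {
    dm <- EBImage::distmap(EBImage::Image(fg * 1))
    # tolerance is in distance-map units; seeds closer than min_separation
    # produce saddles only a fraction of that distance below their maxima,
    # so the merge tolerance is a quarter of the separation
    tol <- max(0.2, params$min_separation_um / mpp / 8)
    ws <- EBImage::watershed(dm, tolerance = tol, ext = 1L)
    lab <- matrix(as.integer(EBImage::imageData(ws)), nrow = nrow(fg))
    n_obj <- max(lab)
    if (n_obj > 0L) {
      shp <- EBImage::computeFeatures.shape(ws)
      mom <- EBImage::computeFeatures.moment(ws)
      area_px <- shp[, "s.area"]
      perim <- pmax(shp[, "s.perimeter"], 1e-9)
      circ <- pmin(4 * pi * area_px / perim^2, 1.5)
      # EBImage works in (x, y) = (dim1, dim2) = our (row, col)
      cr <- as.integer(round(mom[, "m.cx"]))
      cc <- as.integer(round(mom[, "m.cy"]))
      cr <- clip(cr, 1L, nrow(fg)); cc <- clip(cc, 1L, ncol(fg))
      area_um2 <- area_px * mpp^2

      obj_px <- split(which(lab > 0L), lab[lab > 0L])
      mean_od <- vapply(obj_px, function(ix) mean(od[ix]), numeric(1))

      keep <- area_um2 >= params$min_nuclear_area_um2 &
        area_um2 <= params$max_nuclear_area_um2 &
        circ >= params$min_circularity
      # local contrast gate
      if (any(keep)) {
        contrast <- rep(NA_real_, n_obj)
        ann_px <- max(1L, round(params$annulus_um / mpp))
        nr <- nrow(fg); nc <- ncol(fg)
        for (i in which(keep)) {
          ix <- obj_px[[i]]
          rs <- ((ix - 1L) %% nr) + 1L
          cs <- ((ix - 1L) %/% nr) + 1L
          r1 <- max(1L, min(rs) - ann_px); r2 <- min(nr, max(rs) + ann_px)
          c1 <- max(1L, min(cs) - ann_px); c2 <- min(nc, max(cs) + ann_px)
          sub_fg <- fg[r1:r2, c1:c2]
          ann <- od[r1:r2, c1:c2][!sub_fg]
          contrast[i] <- mean_od[i] -
            if (length(ann)) mean(ann) else 0
        }
        keep <- keep & !is.na(contrast) &
          contrast >= params$nuclear_contrast_threshold
      }
      # stroma confinement (centroid on stroma, non-excluded)
      in_stroma <- stroma[cbind(cr, cc)]
      if (!is.null(slide$excluded_mask)) {
        in_stroma <- in_stroma & !slide$excluded_mask[cbind(cr, cc)]
      }
      keep <- keep & in_stroma
      cells <- tibble::tibble(row = cr, col = cc, area_um2 = area_um2,
                              circularity = pmin(circ, 1),
                              mean_od = mean_od)[keep, ]
      # declump: a kept candidate well above the typical single-nucleus
      # area is two fused nuclei; split it along its major axis
      if (is.finite(params$declump_area_um2) && nrow(cells) > 0L) {
        kept_ids <- which(keep)
        extra <- list()
        split_away <- integer(0)
        for (j in which(cells$area_um2 > params$declump_area_um2)) {
          halves <- split_component(obj_px[[kept_ids[j]]], nrow(fg))
          hr <- halves$row; hc <- halves$col
          ok <- all(stroma[cbind(hr, hc)]) &&
            (is.null(slide$excluded_mask) ||
               !any(slide$excluded_mask[cbind(hr, hc)]))
          if (ok) {
            split_away <- c(split_away, j)
            extra[[length(extra) + 1L]] <- tibble::tibble(
              row = hr, col = hc, area_um2 = cells$area_um2[j] / 2,
              circularity = cells$circularity[j],
              mean_od = cells$mean_od[j])
          }
        }
        if (length(split_away)) {
          cells <- dplyr::bind_rows(cells[-split_away, ],
                                    dplyr::bind_rows(extra))
        }
      }
      cells <- exclude_epithelial_nests(cells, od_stroma, params, mpp)
    }
  }
  structure(
    list(slide_id = slide$slide_id,
         cells = cells,
         n_cells = nrow(cells),
         stroma_area_mm2 = seg$stroma_area_mm2,
         mpp = mpp,
         dim = slide_dim(slide)),
    class = "stromal_cell_detection"
  )
}

#' Remove candidates belonging to infiltrating epithelial nests
#'
#' Connected regions of the thresholded detection channel whose area
#' exceeds `nest_area_threshold_um2` are far too large to be single
#' stromal nuclei: they are packed nests of malignant epithelium. Every
#' candidate whose centroid falls inside such a region is removed.
#'
#' @param candidates tibble of candidate cells (`row`, `col`, ...)
#' @param od_raster detection-channel OD matrix
#' @param params a [detection_params()]
#' @param mpp microns per pixel
#' @return the filtered candidate tibble
#' @export
exclude_epithelial_nests <- function(candidates, od_raster, params, mpp) {
  if (nrow(candidates) == 0L || !is.finite(params$nest_area_threshold_um2)) {
    return(candidates)
  }
  fg <- od_raster >= params$min_optical_density
  lab <- label_regions(fg)
  if (max(lab) == 0L) return(candidates)
  areas_um2 <- tabulate(lab[lab > 0L]) * mpp^2
  nest_ids <- which(areas_um2 > params$nest_area_threshold_um2)
  if (!length(nest_ids)) return(candidates)
  in_nest <- lab[cbind(candidates$row, candidates$col)] %in% nest_ids
  candidates[!in_nest, ]
}

#' @export
print.stromal_cell_detection <- function(x, ...) {
  cat(sprintf(
    "<stromal_cell_detection '%s'> %d cells in %.3f mm^2 stroma (%.0f /mm^2)\n",
    x$slide_id, x$n_cells, x$stroma_area_mm2,
    if (x$stroma_area_mm2 > 0) x$n_cells / x$stroma_area_mm2 else 0))
  invisible(x)
}

#' Count detected cells inside a square counting region
#'
#' Counts centroids inside the half-open square
#' `[row0, row0 + side) x [col0, col0 + side)` where `side` is
#' `side_um / mpp` pixels. The 500-um default matches the well-defined
#' 500 x 500 um^2 stromal counting regions used for manual validation.
#'
#' @param detection a `stromal_cell_detection`
#' @param row0,col0 top-left pixel of the region (1-based)
#' @param side_um region side in microns
#' @return integer count
#' @export
count_in_region <- function(detection, row0, col0, side_um = 500) {
  stopifnot(inherits(detection, "stromal_cell_detection"))
  side_px <- side_um / detection$mpp
  if (row0 < 1 || col0 < 1 ||
      row0 + side_px - 1 > detection$dim[1] ||
      col0 + side_px - 1 > detection$dim[2]) {
    stop("counting region extends outside the image", call. = FALSE)
  }
  cells <- detection$cells
  sum(cells$row >= row0 & cells$row < row0 + side_px &
        cells$col >= col0 & cells$col < col0 + side_px)
}

#' Pearson concordance of automated counts with reference counts
#'
#' Used with seeded ground-truth counts acting as the reference reader, as
#' an in-silico analogue of validating automated counts against
#' pathologists' manual counts.
#'
#' @param auto_counts,reference_counts paired numeric vectors (n >= 3)
#' @return tibble (`r`, `n`); `r` is `NA` (with a warning) when either
#'   vector has zero variance
#' @export
concordance_vs_reference <- function(auto_counts, reference_counts) {
  stopifnot(length(auto_counts) == length(reference_counts),
            length(auto_counts) >= 3L)
  if (stats::sd(auto_counts) == 0 || stats::sd(reference_counts) == 0) {
    warning("zero variance in counts; correlation is undefined")
    return(tibble::tibble(r = NA_real_, n = length(auto_counts)))
  }
  tibble::tibble(r = stats::cor(auto_counts, reference_counts),
                 n = length(auto_counts))
}
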