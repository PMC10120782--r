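# Patch features for the tissue classifier.
#
# All features are window statistics (mean/SD) of dense per-pixel maps:
# RGB intensities, hematoxylin and eosin optical densities from fixed
# stain-vector color deconvolution, gradient magnitude of the luminance,
# plus the Shannon entropy of 16-bin luminance histograms. Window sums are
# evaluated from integral images, so a "patch at a point" and a dense grid
# of patches run through the same code path and agree exactly.

# Ruifrok-Johnston H&E stain vectors (unit norm, rows = stains)
HE_STAIN_VECTORS <- rbind(
  hematoxylin = c(0.650, 0.704, 0.286),
  eosin       = c(0.072, 0.990, 0.105),
  residual    = c(0.268, 0.570, 0.776)
)

#' Optical density transform for 8-bit intensities
#'
#' `-log10((I + 1) / 256)`: 0 for saturated white, ~2.408 for 0.
#'
#' @param intensity values in 0..255
#' @return optical densities (non-negative)
#' @export
od_transform <- function(intensity) {
  -log10((intensity + 1) / 256)
}

# per-pixel stain concentrations from RGB OD; returns list(h, e, total)
stain_od_maps <- function(image, stain_vectors = HE_STAIN_VECTORS) {
  d <- dim(image)
  od <- od_transform(image)
  odm <- matrix(od, ncol = 3L)           # pixels x channels
  # OD = conc %*% stain_vectors (rows = stains), so conc = OD %*% V^-1
  conc <- odm %*% solve(stain_vectors)
  list(
    h = matrix(pmax(conc[, 1], 0), d[1], d[2]),
    e = matrix(pmax(conc[, 2], 0), d[1], d[2]),
    total = matrix(rowMeans(odm), d[1], d[2])
  )
}

# central-difference gradient magnitude of a matrix (replicated edges)
gradient_magnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  sqrt(((dn - up) / 2)^2 + ((rt - lf) / 2)^2)
}

N_ENTROPY_BINS <- 16L

feature_names <- function() {
  c("r_mean", "r_sd", "g_mean", "g_sd", "b_mean", "b_sd",
    "h_mean", "h_sd", "e_mean", "e_sd",
    "grad_mean", "grad_sd", "entropy")
}

#' Default configuration of the tissue classifier
#'
#' @param window_um side of the square feature window in microns; the pixel
#'   window is `window_um / mpp`, forced odd (32 um gives 33 px at 1 mpp)
#' @param n_trees random-forest size
#' @param stride_px classification grid stride for [segment_slide()]
#' @param background_luminance luminance threshold (fraction of white) above
#'   which a pixel is background, applied before classification
#' @param seed forest seed
#' @return a `tissue_config` list
#' @export
tissue_config <- function(window_um = 32, n_trees = 100L, stride_px = 4L,
                          background_luminance = 0.9, seed = 7L) {
  structure(list(window_um = window_um, n_trees = as.integer(n_trees),
                 stride_px = as.integer(stride_px),
                 background_luminance = background_luminance,
                 seed = as.integer(seed)),
            class = "tissue_config")
}

window_px_for <- function(slide, window_um) {
  odd_window(um_to_px(window_um, slide$mpp))
}

# precompute integral images of all feature maps for one slide
feature_tables <- function(slide, window_px) {
  k <- (window_px - 1L) %/% 2L
  img <- slide$image
  gray <- slide_gray(slide)
  stains <- stain_od_maps(img)
  grad <- gradient_magnitude(gray)
  maps <- list(r = img[, , 1] / 255, g = img[, , 2] / 255, b = img[, , 3] / 255,
               h = stains$h, e = stains$e, grad = grad)
  pads <- lapply(maps, pad_reflect, k = k)
  ii <- lapply(pads, integral_image)
  ii2 <- lapply(pads, function(m) integral_image(m^2))
  bins <- pmin(floor(gray * N_ENTROPY_BINS), N_ENTROPY_BINS - 1L)
  bins_p <- pad_reflect(bins, k)
  ii_bins <- lapply(seq_len(N_ENTROPY_BINS) - 1L,
                    function(b) integral_image((bins_p == b) * 1))
  list(ii = ii, ii2 = ii2, ii_bins = ii_bins, w = window_px, k = k)
}

features_at <- function(tabs, rows, cols) {
  w <- tabs$w; n <- w^2
  out <- matrix(NA_real_, length(rows), length(feature_names()),
                dimnames = list(NULL, feature_names()))
  stat_pairs <- c(r = "r", g = "g", b = "b", h = "h", e = "e", grad = "grad")
  for (nm in names(stat_pairs)) {
    s1 <- window_sum(tabs$ii[[nm]], rows, cols, w) / n
    s2 <- window_sum(tabs$ii2[[nm]], rows, cols, w) / n
    v <- pmax(s2 - s1^2, 0)
    out[, paste0(nm, "_mean")] <- s1
    out[, paste0(nm, "_sd")] <- sqrt(v)
  }
  ent <- numeric(length(rows))
  for (b in seq_len(N_ENTROPY_BINS)) {
    p <- window_sum(tabs$ii_bins[[b]], rows, cols, w) / n
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log(p[nz])
  }
  out[, "entropy"] <- ent
  out
}

#' Extract patch features at points of a slide
#'
#' Fixed-length vector of local color statistics (mean/SD of RGB and of the
#' hematoxylin/eosin optical-density channels), texture statistics
#' (gradient-magnitude mean/SD) and the local luminance entropy over a
#' square window centered at each point. Borders are handled by reflective
#' padding, so the vector is defined at every pixel and depends only on the
#' image content.
#'
#' @param slide an `sme_slide`
#' @param rows,cols point coordinates (1-based, equal length)
#' @param window_px odd window side in pixels; default derives from the
#'   slide mpp and the 32-um window of [tissue_config()]
#' @return numeric matrix `length(rows) x 13` with named columns
#' @export
extract_features <- function(slide, rows, cols, window_px = NULL) {
  stopifnot(length(rows) == length(cols))
  window_px <- window_px %||% window_px_for(slide, tissue_config()$window_um)
  window_px <- odd_window(window_px)
  d <- slide_dim(slide)
  stopifnot(all(rows >= 1L), all(rows <= d[1]), all(cols >= 1L), all(cols <= d[2]))
  tabs <- feature_tables(slide, window_px)
  features_at(tabs, as.integer(rows), as.integer(cols))
}
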