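# Internal geometry / unit helpers shared across the imaging modules.

#' Convert a pixel count to an area in mm^2
#'
#' @param n_px number of pixels
#' @param mpp microns per pixel
#' @return area in mm^2 (`n_px * mpp^2 / 1e6`)
#' @export
px_to_mm2 <- function(n_px, mpp) {
  n_px * mpp^2 / 1e6
}

um_to_px <- function(um, mpp) um / mpp

# force an odd integer window size, never below `floor_px`
odd_window <- function(px, floor_px = 5L) {
  px <- max(floor_px, round(px))
  if (px %% 2L == 0L) px <- px + 1L
  as.integer(px)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# reflective padding of a matrix by k pixels on each side
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(k < nr, k < nc)
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci, drop = FALSE]
}

# integral image with a leading zero row/column: II[i+1, j+1] = sum m[1:i, 1:j]
integral_image <- function(m) {
  ii <- apply(m, 2L, cumsum)
  ii <- t(apply(ii, 1L, cumsum))
  rbind(0, cbind(0, ii))
}

# sum of the w x w window whose top-left corner (in the padded matrix) is
# (r, c), evaluated from an integral image; r, c vectorised
window_sum <- function(ii, r, c, w) {
  ii[cbind(r + w, c + w)] - ii[cbind(r, c + w)] -
    ii[cbind(r + w, c)] + ii[cbind(r, c)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
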