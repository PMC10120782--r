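#' Construct a slide object
#'
#' A slide bundles an 8-bit RGB raster with its physical pixel size
#' (microns per pixel, mpp) and an optional exclusion mask emulating
#' QC annotations (crush artifacts etc.) that must not contribute to any
#' area or count.
#'
#' @param image numeric or integer array `H x W x 3` with values in 0..255
#' @param mpp microns per pixel; must lie in (0.1, 10] (may be `NA` for a
#'   slide whose scale is still unknown, but segmentation will refuse it)
#' @param slide_id character identifier
#' @param excluded_mask optional logical matrix `H x W`; `TRUE` pixels are
#'   dropped from all downstream areas and counts
#' @return an object of class `sme_slide`
#' @export
new_slide <- function(image, mpp, slide_id = "slide", excluded_mask = NULL) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3] == 3L)
  d <- dim(image)
  if (d[1] < 64L || d[2] < 64L) {
    stop("slide images must be at least 64 x 64 pixels", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("image values must lie in 0..255 (8-bit RGB)", call. = FALSE)
  }
  if (!is.na(mpp) && (mpp <= 0.1 || mpp > 10)) {
    stop("mpp must lie in (0.1, 10] microns per pixel", call. = FALSE)
  }
  if (!is.null(excluded_mask)) {
    stopifnot(is.matrix(excluded_mask),
              all(dim(excluded_mask) == d[1:2]))
    excluded_mask <- excluded_mask > 0
  }
  structure(
    list(slide_id = as.character(slide_id),
         image = image,
         mpp = as.numeric(mpp),
         excluded_mask = excluded_mask),
    class = "sme_slide"
  )
}

#' @export
print.sme_slide <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<sme_slide '%s'> %d x %d px, mpp = %s%s\n",
              x$slide_id, d[1], d[2], format(x$mpp),
              if (!is.null(x$excluded_mask)) ", with exclusion mask" else ""))
  invisible(x)
}

slide_dim <- function(slide) dim(slide$image)[1:2]

# luminance in [0, 1] (Rec. 601 weights)
slide_gray <- function(slide) {
  img <- slide$image / 255
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Write a slide image to disk
#'
#' Writes the RGB raster as an 8-bit PNG or TIFF depending on the file
#' extension. The mpp and exclusion mask are not embedded; keep them in the
#' scene parameter YAML.
#'
#' @param slide an `sme_slide`
#' @param path output path ending in `.png`, `.tif` or `.tiff`
#' @return `path`, invisibly
#' @export
write_slide <- function(slide, path) {
  img <- slide$image / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(aperm(img, c(1, 2, 3)), target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, where = path, bits.per.sample = 8L)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a slide image from disk
#'
#' @param path PNG or TIFF path written by [write_slide()] (8-bit RGB)
#' @param mpp microns per pixel of the raster
#' @param slide_id identifier; defaults to the file stem
#' @return an `sme_slide`
#' @export
read_slide <- function(path, mpp, slide_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  img <- array(as.integer(round(img * 255)), dim(img))
  new_slide(img, mpp = mpp,
            slide_id = slide_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a label raster as a single-channel image
#'
#' Labels use the fixed coding 0 = background, 1 = tumor, 2 = stroma,
#' 3 = excluded, stored in the low bits of an 8-bit single-channel TIFF/PNG.
#'
#' @param labels integer matrix of labels in 0..3
#' @param path output path (`.png`, `.tif`, `.tiff`)
#' @return `path`, invisibly
#' @export
write_label_raster <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels %in% 0:3))
  m <- labels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(m, target = path)
  else tiff::writeTIFF(m, where = path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a label raster written by [write_label_raster()]
#'
#' @param path image path
#' @return integer matrix of labels
#' @export
read_label_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow = nrow(m))
}
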