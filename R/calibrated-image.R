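#' Calibrated micrograph
#'
#' A thin container pairing raster pixel data with the physical pixel size
#' and imaging modality. Brightfield images carry an RGB array
#' (`height x width x 3`, values in `[0, 1]`); fluorescence images carry a
#' single-channel matrix. All downstream geometry (band widths, bundle
#' areas) is expressed in micrometres through `px_size_um`.
#'
#' @param pixels numeric matrix (fluorescence) or `h x w x 3` array
#'   (brightfield), values in `[0, 1]`.
#' @param px_size_um physical size of one pixel in micrometres (> 0).
#' @param modality one of `"brightfield_dab"`, `"brightfield_sirius"`,
#'   `"fluorescence"`.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels,
                             px_size_um,
                             modality = c("brightfield_dab",
                                          "brightfield_sirius",
                                          "fluorescence")) {
  modality <- match.arg(modality)
  if (!is.numeric(px_size_um) || length(px_size_um) != 1L || px_size_um <= 0) {
    abort("`px_size_um` must be a single positive number.")
  }
  dims <- dim(pixels)
  if (is.null(dims) || !(length(dims) %in% c(2L, 3L))) {
    abort("`pixels` must be a matrix or a height x width x 3 array.")
  }
  if (length(dims) == 3L && dims[3] != 3L) {
    abort("multi-channel images must have exactly 3 channels (RGB).")
  }
  if (any(dims[1:2] < 64L)) {
    abort("image must be at least 64 x 64 pixels.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    abort("pixel values must lie in [0, 1] with no missing values.")
  }
  structure(
    list(pixels = pixels, px_size_um = px_size_um, modality = modality),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<calibrated_image> %d x %d px (%s), %.3g um/px, %s\n",
    d[1], d[2],
    if (length(d) == 3L) "RGB" else "1 channel",
    x$px_size_um, x$modality
  ))
  invisible(x)
}

is_brightfield <- function(img) startsWith(img$modality, "brightfield")

#' Image dimensions in pixels (rows, columns)
#' @param img a [calibrated_image()].
#' @return integer vector `c(height, width)`.
#' @export
image_dim <- function(img) dim(img$pixels)[1:2]

# Rec.709 luma of an RGB array; identity on single-channel images.
luminance <- function(pixels) {
  if (length(dim(pixels)) == 2L) return(pixels)
  0.2126 * pixels[, , 1] + 0.7152 * pixels[, , 2] + 0.0722 * pixels[, , 3]
}

# per-pixel chroma (max - min channel); 0 for single-channel images
chroma <- function(pixels) {
  if (length(dim(pixels)) == 2L) return(array(0, dim(pixels)))
  pmax(pixels[, , 1], pixels[, , 2], pixels[, , 3]) -
    pmin(pixels[, , 1], pixels[, , 2], pixels[, , 3])
}

#' Read a calibrated image from TIFF or PNG
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @inheritParams calibrated_image
#' @return A [calibrated_image()].
#' @export
read_calibrated_image <- function(path, px_size_um, modality) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(sprintf("unsupported image extension '%s'", ext))
  )
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3] # drop alpha
  calibrated_image(px, px_size_um = px_size_um, modality = modality)
}

#' Write a calibrated image to TIFF or PNG
#'
#' @param img a [calibrated_image()].
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(img$pixels, path),
    png = png::writePNG(img$pixels, path),
    abort(sprintf("unsupported image extension '%s'", ext))
  )
  invisible(path)
}
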