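#' RGB histology image container
#'
#' A thin container for an 8-bit RGB image: an `H x W x 3` numeric array with
#' channel values in `[0, 255]` (0-based `(row, col)` convention, row 0 at the
#' top) plus the physical pixel size in microns. All gonadquant image
#' operations take and return this class.
#'
#' @param pixels Numeric `H x W x 3` array with values in `[0, 255]`.
#' @param microns_per_pixel Positive scalar, physical edge length of one pixel
#'   in microns. The study's scans are 0.25 um/px at 20x; after the standard
#'   downsampling by 8 one pixel is 2 um.
#' @return An object of class `rgb_image`.
#' @examples
#' px <- array(255, dim = c(4, 4, 3))
#' img <- rgb_image(px, microns_per_pixel = 2)
#' dim(img$pixels)
#' @export
rgb_image <- function(pixels, microns_per_pixel = 2) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("`pixels` must lie in [0, 255] with no missing values.")
  }
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      microns_per_pixel <= 0) {
    abort("`microns_per_pixel` must be a positive scalar.")
  }
  structure(
    list(pixels = pixels, microns_per_pixel = as.numeric(microns_per_pixel)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<rgb_image> %d x %d px, %.4g um/px (%.3g x %.3g mm)\n",
    d[1], d[2], x$microns_per_pixel,
    d[1] * x$microns_per_pixel / 1000, d[2] * x$microns_per_pixel / 1000
  ))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read an RGB image from PNG or TIFF
#'
#' Channel values are rescaled to `[0, 255]`. Grayscale files are replicated
#' across the three channels; an alpha channel, if present, is dropped.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param microns_per_pixel Pixel size of the file in microns (default 0.25,
#'   the native 20x scan resolution).
#' @return An [rgb_image].
#' @export
read_rgb_image <- function(path, microns_per_pixel = 0.25) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("Cannot read image: no file at '%s'.", as.character(path)[1]))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image format '%s' for '%s' (use PNG or TIFF).",
                  ext, path))
  )
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] >= 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  rgb_image(round(raw * 255), microns_per_pixel = microns_per_pixel)
}

#' Write an RGB image to PNG or TIFF
#'
#' @param image An [rgb_image].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, target = path),
    tif = ,
    tiff = tiff::writeTIFF(arr, where = path),
    abort(sprintf("Unsupported image format '%s' (use PNG or TIFF).", ext))
  )
  invisible(path)
}

#' Write a binary mask as a 1-bit style PNG
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' Read a mask PNG back as a logical matrix
#'
#' Pixels with value > 0.5 are foreground.
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw > 0.5
}
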