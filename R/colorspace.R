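# Colour-space conversions used by the threshold segmentation: the classical
# HSI model (intensity thresholds isolate tissue from the white background)
# and CIELAB (L*/a* thresholds isolate the tubule stain).

#' Convert an RGB image to Hue, Saturation, Intensity channels
#'
#' Classical HSI model: `I = (R + G + B) / (3 * 255)`,
#' `S = 1 - min(R, G, B) / mean(R, G, B)` (0 for black pixels), and H the
#' standard angular hue in degrees `[0, 360)`; achromatic pixels (undefined
#' hue) map to `H = 0`.
#'
#' @param image An [rgb_image].
#' @return A list of numeric matrices `h`, `s`, `i`.
#' @examples
#' img <- rgb_image(array(c(255, 0, 0), dim = c(1, 1, 3)))
#' to_hsi(img) # pure red: H = 0, S = 1, I = 1/3
#' @export
to_hsi <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image$pixels)
  r <- matrix(image$pixels[, , 1], d[1], d[2])
  g <- matrix(image$pixels[, , 2], d[1], d[2])
  b <- matrix(image$pixels[, , 3], d[1], d[2])
  s <- r + g + b
  i <- s / (3 * 255)
  mn <- pmin(r, g, b)
  sat <- ifelse(s == 0, 0, 1 - 3 * mn / s)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- ifelse(den == 0, 0, acos(pmin(pmax(num / den, -1), 1)) * 180 / pi)
  h <- ifelse(b > g, 360 - theta, theta)
  h[den == 0] <- 0
  list(h = h, s = sat, i = i)
}

#' Convert an RGB image to CIE L*a*b* channels
#'
#' Standard sRGB -> XYZ (D65) -> L*a*b* conversion. `L*` is lightness in
#' `[0, 100]`; `a*` runs green (negative) to red (positive); `b*` runs blue
#' to yellow.
#'
#' @param image An [rgb_image].
#' @return A list of numeric matrices `l`, `a`, `b`.
#' @export
to_lab <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image$pixels)
  m <- matrix(image$pixels, ncol = 3) / 255
  lab <- convertColor(m, from = "sRGB", to = "Lab")
  list(
    l = matrix(lab[, 1], d[1], d[2]),
    a = matrix(lab[, 2], d[1], d[2]),
    b = matrix(lab[, 3], d[1], d[2])
  )
}

# Inverse of to_lab(); returns an rgb_image with 8-bit rounded channels.
lab_to_image <- function(l, a, b, microns_per_pixel) {
  lab <- cbind(as.vector(l), as.vector(a), as.vector(b))
  srgb <- convertColor(lab, from = "Lab", to = "sRGB")
  srgb <- pmin(pmax(srgb, 0), 1)
  px <- array(floor(srgb * 255 + 0.5), dim = c(nrow(l), ncol(l), 3))
  rgb_image(px, microns_per_pixel = microns_per_pixel)
}
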