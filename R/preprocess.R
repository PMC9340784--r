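# Loading-side preprocessing: block-mean downsampling and Reinhard-style
# stain colour normalisation in CIELAB. Both run before any segmentation.

#' Downsample an image by block averaging
#'
#' Each output pixel is the mean of its `factor x factor` source block
#' (partial edge blocks are averaged over the pixels available), rounded half
#' up to an integer. Block averaging is area-preserving, so downstream area
#' indices are unbiased; `microns_per_pixel` is multiplied by `factor`.
#' The analysis convention for 20x whole-section scans is `factor = 8`.
#'
#' @param image An [rgb_image].
#' @param factor Positive integer downsampling factor; `1` returns the image
#'   unchanged.
#' @return An [rgb_image] of dimensions `ceiling(H / factor) x ceiling(W / factor)`.
#' @examples
#' img <- rgb_image(array(rep(c(10, 20, 30, 40), 3), dim = c(2, 2, 3)))
#' downsample(img, 2)$pixels[1, 1, 1] # 25
#' @export
downsample <- function(image, factor) {
  stopifnot(inherits(image, "rgb_image"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    abort("`factor` must be a positive integer.")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  d <- dim(image$pixels)
  ri <- ceiling(seq_len(d[1]) / factor)  # output row of each input row
  ci <- ceiling(seq_len(d[2]) / factor)
  ho <- ri[d[1]]; wo <- ci[d[2]]
  counts <- tabulate(ri, ho) %o% tabulate(ci, wo)
  out <- array(0, dim = c(ho, wo, 3))
  for (k in 1:3) {
    sums <- rowsum(t(rowsum(image$pixels[, , k], ri)), ci)
    out[, , k] <- floor(t(sums) / counts + 0.5)
  }
  rgb_image(out, microns_per_pixel = image$microns_per_pixel * factor)
}

#' Lab statistics of a reference image for colour normalisation
#'
#' Computes the per-channel mean and standard deviation in L*a*b* space of a
#' designated reference image (optionally restricted to a mask, e.g. tissue
#' only). These six numbers define the target of [color_normalize()].
#'
#' @param image An [rgb_image].
#' @param mask Optional logical matrix restricting the statistics.
#' @return An object of class `color_reference`: list with `mean` and `sd`,
#'   each a named length-3 numeric (`l`, `a`, `b`).
#' @export
color_reference <- function(image, mask = NULL) {
  lab <- to_lab(image)
  vals <- lapply(lab, function(ch) if (is.null(mask)) as.vector(ch) else ch[mask])
  m <- vapply(vals, mean, numeric(1))
  s <- vapply(vals, sd, numeric(1))
  names(m) <- names(s) <- c("l", "a", "b")
  if (any(!is.finite(s)) || any(s <= 0)) {
    warn("Reference image has a constant Lab channel; its sd is set to 1 (mean shift only).")
    s[!is.finite(s) | s <= 0] <- 1
  }
  structure(list(mean = m, sd = s), class = "color_reference")
}

#' Reinhard-style stain colour normalisation
#'
#' Transfers the global colour statistics of a reference slide onto an image:
#' converts to L*a*b*, shifts and scales each channel so its mean and
#' standard deviation match the reference, converts back to sRGB and clips to
#' `[0, 255]`. Channels with zero variance in the input are mean-shifted only
#' (with a warning). Used to align staining intensity across slides before
#' thresholding.
#'
#' @param image An [rgb_image].
#' @param ref A [color_reference].
#' @return A normalised [rgb_image].
#' @export
color_normalize <- function(image, ref) {
  stopifnot(inherits(image, "rgb_image"), inherits(ref, "color_reference"))
  lab <- to_lab(image)
  out <- vector("list", 3)
  for (k in 1:3) {
    ch <- lab[[k]]
    m <- mean(ch); s <- sd(as.vector(ch))
    if (!is.finite(s) || s == 0) {
      warn(sprintf("Channel %s has zero variance; mean shift only.",
                   c("L*", "a*", "b*")[k]))
      out[[k]] <- ch - m + ref$mean[k]
    } else {
      out[[k]] <- (ch - m) / s * ref$sd[k] + ref$mean[k]
    }
  }
  lab_to_image(out[[1]], out[[2]], out[[3]], image$microns_per_pixel)
}

#' Downsample a logical mask by block majority
#'
#' Companion to [downsample()] for ground-truth masks: each output pixel is
#' TRUE when at least half of its source block is TRUE. Used to bring truth
#' masks to the working resolution, e.g. to build classifier training frames
#' on downsampled phantoms.
#'
#' @param mask Logical matrix.
#' @param factor Positive integer downsampling factor.
#' @return Logical matrix of dimensions `ceiling(dim / factor)`.
#' @export
downsample_mask <- function(mask, factor) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    abort("`factor` must be a positive integer.")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(mask)
  ri <- ceiling(seq_len(nrow(mask)) / factor)
  ci <- ceiling(seq_len(ncol(mask)) / factor)
  counts <- tabulate(ri, max(ri)) %o% tabulate(ci, max(ci))
  sums <- t(rowsum(t(rowsum(mask * 1, ri)), ci))
  out <- sums / counts >= 0.5
  dimnames(out) <- NULL
  out
}
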