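# Three-tissue segmentation: whole section by an HSI intensity threshold,
# gonadal tubules by CIELAB L*/a* thresholds, storage tissue by a
# random-forest pixel classifier over colour + local texture features.

#' Segment the whole tissue section
#'
#' Tissue pixels are those with HSI intensity below a threshold (the stained
#' section is darker than the white slide background). The threshold defaults
#' to the ISODATA intermeans value on the intensity channel; morphological
#' closing (disc radius 2 px) and hole filling follow, components below `min_component_px`
#' are dropped, and `exclusion` pixels (e.g. manually outlined gills, which
#' are removed before analysis) are forced to background.
#'
#' @param image An [rgb_image].
#' @param exclusion Optional logical matrix of pixels to exclude.
#' @param threshold Fixed intensity threshold in `[0, 1]`; `NULL` (default)
#'   uses the automatic method.
#' @param method Automatic threshold method: `"otsu3"` (default for the
#'   whole-tissue cut: upper threshold of a three-class Otsu, robust to the
#'   trimodal background/tissue/stain histogram), `"otsu"` or `"isodata"`
#'   (Ridler-Calvard iterative intermeans).
#' @param closing_radius Disc radius for morphological closing (px).
#' @param min_component_px Minimum connected-component size kept.
#' @return Logical tissue mask with attribute `threshold_log` (list of the
#'   parameters actually used).
#' @export
segment_whole <- function(image, exclusion = NULL, threshold = NULL,
                          closing_radius = 2, min_component_px = 64,
                          method = c("otsu3", "otsu", "isodata")) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image$pixels)[1:2]
  if (!is.null(exclusion) && !identical(dim(exclusion), d)) {
    abort("`exclusion` must match the image shape.")
  }
  method <- match.arg(method)
  i_ch <- to_hsi(image)$i
  thr <- threshold %||% if (method == "otsu3") {
    otsu_upper_threshold(as.vector(i_ch))
  } else {
    auto_threshold(as.vector(i_ch), method)
  }
  mask <- i_ch < thr
  mask <- close_and_fill(mask, radius = closing_radius, fill = TRUE)
  dropped <- drop_small_components(mask, min_component_px)
  mask <- dropped$mask
  if (!is.null(exclusion)) mask[exclusion] <- FALSE
  if (!any(mask)) {
    abort("No tissue found: the intensity threshold left an empty mask.")
  }
  attr(mask, "threshold_log") <- list(
    intensity_threshold = thr, closing_radius = closing_radius,
    min_component_px = min_component_px,
    n_small_dropped = dropped$n_dropped
  )
  mask
}

#' Segment the gonadal tubules inside the tissue mask
#'
#' Tubule pixels satisfy `L* < l_threshold` and `a* >= a_threshold` within
#' the whole-tissue mask: the blue-violet tubule stain is darker than the
#' pink connective/storage tissue and at least as red-shifted. Thresholds
#' default to the ISODATA intermeans value computed on the respective channel
#' within the mask; both inequalities can be flipped for other stains. An
#' empty result is valid (resting-stage sections have scarce tubules).
#'
#' @param image An [rgb_image].
#' @param whole Logical whole-tissue mask.
#' @param l_threshold,a_threshold Fixed thresholds; `NULL` uses the
#'   automatic method within `whole`.
#' @inheritParams segment_whole
#' @param l_below,a_above Direction of each rule (defaults match the
#'   trichrome palette).
#' @param closing_radius Disc radius for morphological closing (px).
#' @return Logical GT mask (subset of `whole`) with attribute `threshold_log`.
#' @export
segment_gt <- function(image, whole, l_threshold = NULL, a_threshold = NULL,
                       l_below = TRUE, a_above = TRUE, closing_radius = 2,
                       method = c("otsu", "isodata")) {
  stopifnot(inherits(image, "rgb_image"), is.logical(whole))
  if (!any(whole)) abort("`whole` mask is empty.")
  lab <- to_lab(image)
  t_l <- l_threshold %||% auto_threshold(lab$l[whole], method)
  t_a <- a_threshold %||% auto_threshold(lab$a[whole], method)
  sel_l <- if (l_below) lab$l < t_l else lab$l >= t_l
  sel_a <- if (a_above) lab$a >= t_a else lab$a < t_a
  mask <- sel_l & sel_a & whole
  if (any(mask)) mask <- close_and_fill(mask, radius = closing_radius, fill = TRUE)
  mask <- mask & whole
  attr(mask, "threshold_log") <- list(
    l_threshold = t_l, a_threshold = t_a,
    l_below = l_below, a_above = a_above, closing_radius = closing_radius
  )
  mask
}

#' Fit the storage-tissue pixel classifier
#'
#' Random-forest pixel classification over per-pixel colour and local texture
#' features (R, G, B plus their 3x3 neighbourhood mean and standard
#' deviation), the same family of classifier as interactive pixel-labelling
#' tools. Reproducible for a fixed seed.
#'
#' @param labeled_pixels Data frame with feature columns (see
#'   [pixel_features()]) and a `class` column (factor or character) holding
#'   at least two classes with at least 50 pixels each.
#' @param num_trees Number of trees (default 100).
#' @param seed Integer seed for the forest.
#' @return An object of class `st_classifier`.
#' @export
fit_st_classifier <- function(labeled_pixels, num_trees = 100, seed = 1) {
  stopifnot(is.data.frame(labeled_pixels), "class" %in% names(labeled_pixels))
  counts <- table(labeled_pixels$class)
  counts <- counts[counts > 0]
  if (length(counts) < 2) {
    abort("Need at least two pixel classes to train the classifier.")
  }
  if (any(counts < 50)) {
    abort("Each pixel class needs at least 50 labeled pixels.")
  }
  df <- as.data.frame(labeled_pixels)
  df$class <- factor(df$class)
  features <- setdiff(names(df), "class")
  fit <- ranger::ranger(
    dependent.variable.name = "class", data = df[c(features, "class")],
    num.trees = num_trees, seed = seed, num.threads = 1
  )
  structure(list(forest = fit, features = features, seed = seed),
            class = "st_classifier")
}

#' Per-pixel colour and texture features
#'
#' R, G, B channel values plus the 3x3 neighbourhood mean and standard
#' deviation of each channel (replicated boundary), the feature set consumed
#' by [fit_st_classifier()] and [segment_st()].
#'
#' @param image An [rgb_image].
#' @param which Optional logical mask or integer vector of pixel indices to
#'   extract; default all pixels.
#' @return A tibble with 9 feature columns, one row per pixel.
#' @export
pixel_features <- function(image, which = NULL) {
  stopifnot(inherits(image, "rgb_image"))
  box <- matrix(1 / 9, 3, 3)
  feats <- list()
  for (ch in 1:3) {
    x <- image$pixels[, , ch]
    mu <- local_filter(x, box)
    mu2 <- local_filter(x^2, box)
    sdv <- sqrt(pmax(mu2 - mu^2, 0))
    nm <- c("r", "g", "b")[ch]
    feats[[nm]] <- x
    feats[[paste0(nm, "_mean3")]] <- mu
    feats[[paste0(nm, "_sd3")]] <- sdv
  }
  idx <- if (is.null(which)) seq_along(feats[[1]]) else which
  as_tibble(lapply(feats, function(m) as.numeric(m[idx])))
}

# 2D convolution with replicated borders via padding + EBImage::filter2.
local_filter <- function(x, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- x[c(rep(1L, r), 1:h, rep(h, r)), c(rep(1L, r), 1:w, rep(w, r))]
  out <- EBImage::filter2(xp, kern, boundary = "circular")
  matrix(as.numeric(out), nrow(xp), ncol(xp))[(r + 1):(r + h), (r + 1):(r + w)]
}

#' Segment the storage tissue with a trained pixel classifier
#'
#' Applies an [st_classifier][fit_st_classifier()] to the pixels of
#' `whole & !gt`; pixels predicted as `"storage"` form the ST mask, which is
#' disjoint from GT by construction (GT has priority where a storage
#' prediction falls inside a tubule).
#'
#' @param image An [rgb_image].
#' @param whole,gt Logical masks from [segment_whole()] / [segment_gt()].
#' @param model A trained `st_classifier`.
#' @return Logical ST mask, disjoint from `gt`, subset of `whole`.
#' @export
segment_st <- function(image, whole, gt, model) {
  stopifnot(inherits(image, "rgb_image"), is.logical(whole), is.logical(gt))
  if (!inherits(model, "st_classifier")) {
    abort("`model` must be a trained st_classifier (see fit_st_classifier()).")
  }
  target <- whole & !gt
  st <- matrix(FALSE, nrow(whole), ncol(whole))
  if (!any(target)) return(st)
  idx <- which(target)
  feats <- pixel_features(image, which = idx)
  pred <- stats::predict(model$forest, data = as.data.frame(feats),
                         num.threads = 1, seed = model$seed)$predictions
  st[idx[pred == "storage"]] <- TRUE
  st
}

#' Labeled training pixels from reference masks
#'
#' Builds a [fit_st_classifier()] training frame from an image with known
#' class masks (typically a phantom and its truth), sampling up to
#' `max_per_class` pixels per class: `"storage"` from the ST mask,
#' `"tubule"` from GT, `"connective"` from the remaining tissue.
#'
#' @param image An [rgb_image].
#' @param whole,gt,st Logical masks.
#' @param max_per_class Per-class pixel cap (default 4000).
#' @param seed Sampling seed.
#' @return Tibble of features plus a `class` column.
#' @export
st_training_frame <- function(image, whole, gt, st, max_per_class = 4000,
                              seed = 1) {
  withr::with_seed(seed, {
    pools <- list(
      storage = which(st),
      tubule = which(gt),
      connective = which(whole & !gt & !st)
    )
    pools <- pools[vapply(pools, length, integer(1)) > 0]
    out <- purrr::map2(pools, names(pools), function(idx, cl) {
      if (length(idx) > max_per_class) idx <- sample(idx, max_per_class)
      f <- pixel_features(image, which = idx)
      f$class <- cl
      f
    })
    dplyr::bind_rows(out)
  })
}

#' Compose the three tissue masks
#'
#' Bundles whole/GT/ST into a `tissue_masks` object, enforcing the
#' invariants GT within whole, ST within whole and GT disjoint from ST (GT
#' has priority over conflicting ST predictions).
#'
#' @param whole,gt,st Logical masks of one shape.
#' @param threshold_log Optional list of the thresholds/parameters used.
#' @return An object of class `tissue_masks`.
#' @export
tissue_masks <- function(whole, gt, st = NULL, threshold_log = list()) {
  d <- dim(whole)
  if (is.null(st)) st <- matrix(FALSE, d[1], d[2])
  if (!identical(dim(gt), d) || !identical(dim(st), d)) {
    abort("Masks must share one shape.")
  }
  gt <- gt & whole
  st <- st & whole & !gt
  structure(list(whole = whole, gt = gt, st = st,
                 threshold_log = threshold_log),
            class = "tissue_masks")
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat(sprintf(
    "<tissue_masks> %d x %d px | whole %d px, GT %d px, ST %d px\n",
    nrow(x$whole), ncol(x$whole), sum(x$whole), sum(x$gt), sum(x$st)
  ))
  invisible(x)
}

# Automatic single threshold on a numeric vector: Otsu (EBImage backend,
# 256 levels over the data range) or Ridler-Calvard ISODATA (iterative
# intermeans, robust when one class holds a small share of the pixels).
auto_threshold <- function(x, method = c("otsu", "isodata"), levels = 256L) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  if (method == "otsu") {
    return(EBImage::otsu(EBImage::Image(matrix(x, ncol = 1)), range = rng,
                         levels = levels))
  }
  t <- mean(x)
  for (iter in seq_len(100L)) {
    lo <- x[x < t]; hi <- x[x >= t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-8 * diff(rng)) { t <- t_new; break }
    t <- t_new
  }
  t
}

# Upper threshold of a two-threshold (three-class) Otsu. The intensity
# histogram of a slide scan is typically trimodal (white background, pale
# connective/storage tissue, dark tubule stain); a single two-class
# threshold can lock onto the wrong valley, so the background/tissue cut is
# taken as the upper of the two thresholds maximising the three-class
# between-class variance.
otsu_upper_threshold <- function(x, levels = 128L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, all.inside = TRUE), levels))
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  cp <- cumsum(p)
  cm <- cumsum(p * mids)
  # class = (1..t1], (t1..t2], (t2..levels]
  w1 <- matrix(cp, levels, levels)                 # rows t1
  w12 <- matrix(cp, levels, levels, byrow = TRUE)  # cols t2
  m1 <- matrix(cm, levels, levels)
  m12 <- matrix(cm, levels, levels, byrow = TRUE)
  w2 <- w12 - w1
  w3 <- 1 - w12
  m2 <- m12 - m1
  m3 <- cm[levels] - m12
  crit <- m1^2 / w1 + m2^2 / w2 + m3^2 / w3
  crit[!is.finite(crit)] <- -Inf
  crit[!upper.tri(crit)] <- -Inf                   # need t1 < t2
  best <- arrayInd(which.max(crit), dim(crit))
  br[best[2] + 1L]
}
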