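# Per-tubule morphometry: 8-connected labeling of the GT mask, area /
# Crofton perimeter / circularity / equivalent-ellipse axes / Gravelius
# compactness per tubule, and the K < 1.7 circularity filter used to keep
# only tubules cut close to perpendicular to their axis.

#' Label tubules in a GT mask
#'
#' 8-connected components of `gt` with at least `min_area_px` pixels are
#' labeled `1..n` in raster order of their first pixel; smaller components
#' are discarded and counted in the attached log.
#'
#' @param gt Logical GT mask.
#' @param min_area_px Minimum component size in pixels (default 30, about
#'   120 um2 at 2 um/px — suppresses stain specks).
#' @return Integer label matrix with attributes `n_labels`, `n_discarded`,
#'   `px_discarded`.
#' @export
label_tubules <- function(gt, min_area_px = 30) {
  stopifnot(is.logical(gt), is.matrix(gt))
  lab <- label_components8(gt)
  n_all <- max(lab)
  px_disc <- 0L
  if (n_all > 0 && min_area_px > 1) {
    sizes <- tabulate(lab[lab > 0L], n_all)
    keep <- which(sizes >= min_area_px)
    px_disc <- sum(sizes[setdiff(seq_len(n_all), keep)])
    relab <- integer(n_all)
    relab[keep] <- seq_along(keep)  # keep raster order among survivors
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  n <- max(lab)
  attr(lab, "n_labels") <- n
  attr(lab, "n_discarded") <- n_all - n
  attr(lab, "px_discarded") <- px_disc
  lab
}

#' Measure every labeled tubule
#'
#' For each labeled region: pixel area (and um2), perimeter by the
#' 4-direction Crofton estimator, circularity `4 * pi * A / P^2`,
#' equivalent-ellipse major/minor axis lengths from the second central
#' moments (axis length `4 * sqrt(eigenvalue)`), Gravelius compactness
#' [gravelius()], centroid, and whether the region touches the image border.
#'
#' @param labels Integer label matrix from [label_tubules()].
#' @param microns_per_pixel Pixel size in microns.
#' @return A tibble with one row per tubule (columns `label`, `area_px`,
#'   `area_um2`, `perimeter_px`, `perimeter_um`, `circularity`,
#'   `major_axis_px`, `minor_axis_px`, `gravelius_k`, `centroid_row`,
#'   `centroid_col`, `touches_border`).
#' @export
measure_tubules <- function(labels, microns_per_pixel = 2) {
  stopifnot(is.matrix(labels))
  n <- max(labels)
  h <- nrow(labels); w <- ncol(labels)
  if (n < 1) {
    return(tibble(
      label = integer(0), area_px = integer(0), area_um2 = numeric(0),
      perimeter_px = numeric(0), perimeter_um = numeric(0),
      circularity = numeric(0), major_axis_px = numeric(0),
      minor_axis_px = numeric(0), gravelius_k = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0),
      touches_border = logical(0)
    ))
  }
  purrr::map_dfr(seq_len(n), function(lb) {
    idx <- which(labels == lb)
    measure_region(idx, h, w, microns_per_pixel, label = lb)
  })
}

# Measure one region given its linear pixel indices.
measure_region <- function(idx, h, w, microns_per_pixel, label = 1L) {
  if (!length(idx)) abort("Region is empty.")
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  area <- length(idx)
  cy <- mean(r); cx <- mean(c)
  mu20 <- mean((r - cy)^2)
  mu02 <- mean((c - cx)^2)
  mu11 <- mean((r - cy) * (c - cx))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(pmax((tr / 2)^2 - det, 0))
  lam1 <- tr / 2 + disc
  lam2 <- pmax(tr / 2 - disc, 0)
  # perimeter on the region's padded bounding box
  sub <- matrix(FALSE, diff(range(r)) + 1L, diff(range(c)) + 1L)
  sub[cbind(r - min(r) + 1L, c - min(c) + 1L)] <- TRUE
  per <- crofton_perimeter(sub)
  tibble(
    label = as.integer(label),
    area_px = area,
    area_um2 = area * microns_per_pixel^2,
    perimeter_px = per,
    perimeter_um = per * microns_per_pixel,
    circularity = 4 * pi * area / per^2,
    major_axis_px = 4 * sqrt(lam1),
    minor_axis_px = 4 * sqrt(lam2),
    gravelius_k = gravelius(per, area),
    centroid_row = cy, centroid_col = cx,
    touches_border = any(r == 1L | r == h | c == 1L | c == w)
  )
}

#' Gravelius compactness coefficient
#'
#' `K = P / (2 * sqrt(pi * A))`, i.e. the region's perimeter relative to the
#' perimeter of the disk of equal area (the often-quoted `0.28 * P / sqrt(A)`
#' uses the rounded constant; the exact `1 / (2 * sqrt(pi)) ~ 0.2821` is used
#' here so that `K = 1` holds exactly for a circle). `K` grows with
#' elongation; tubule cross sections are kept when `K < 1.7`.
#'
#' @param perimeter,area Positive reals (any consistent units).
#' @return `K`, a dimensionless real `>= 1` for exact shapes.
#' @examples
#' gravelius(2 * pi * 10, pi * 100) # 1 for a circle
#' @export
gravelius <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0)) {
    abort("`perimeter` and `area` must be positive.")
  }
  perimeter / (2 * sqrt(pi * area))
}

#' Keep tubules with circular cross sections
#'
#' Filters tubule records to `gravelius_k < k_max` (strict), the criterion
#' used before counting tubules and averaging their areas so that oblique or
#' tangential cuts do not distort the per-tubule statistics. Order is
#' preserved; idempotent.
#'
#' @param records Tibble from [measure_tubules()].
#' @param k_max Strict upper bound on K (default 1.7).
#' @return The filtered tibble.
#' @export
filter_circular <- function(records, k_max = 1.7) {
  stopifnot(is.data.frame(records))
  dplyr::filter(records, .data$gravelius_k < k_max)
}

#' Representativeness of the circular-tubule subset
#'
#' Checks that the tubules kept by [filter_circular()] are a representative
#' share of all tubules across animals: a one-sample Student t-test of the
#' per-animal kept/total proportions against the pooled overall proportion.
#' Animals with zero tubules are excluded with a warning; if the proportions
#' have zero variance the test is degenerate and reported as no difference.
#'
#' @param counts Data frame with columns `animal`, `kept`, `total`.
#' @return One-row tibble: `n_animals`, `pooled_proportion`,
#'   `mean_proportion`, `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `stars`, `degenerate_flag`.
#' @export
representativeness <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("animal", "kept", "total") %in% names(counts)))
  if (any(counts$kept > counts$total) || any(counts$kept < 0)) {
    abort("Need 0 <= kept <= total for every animal.")
  }
  empty <- counts$total == 0
  if (any(empty)) {
    warn(sprintf("Excluding %d animal(s) with zero tubules: %s",
                 sum(empty), paste(counts$animal[empty], collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) < 2) abort("Need at least two animals with tubules.")
  props <- counts$kept / counts$total
  pooled <- sum(counts$kept) / sum(counts$total)
  if (sd(props) == 0) {
    return(tibble(
      n_animals = nrow(counts), pooled_proportion = pooled,
      mean_proportion = mean(props), t_statistic = 0,
      degrees_of_freedom = nrow(counts) - 1, p_value = 1,
      stars = "ns", degenerate_flag = TRUE
    ))
  }
  tt <- t.test(props, mu = pooled)
  tibble(
    n_animals = nrow(counts), pooled_proportion = pooled,
    mean_proportion = mean(props),
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = tt$p.value,
    stars = significance_stars(tt$p.value),
    degenerate_flag = FALSE
  )
}
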