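# Synthetic trichrome-like slide phantoms. A phantom is a tissue blob
# (squircle) on a white background containing a gonadal area (GA): a
# concentric region tiled with elliptical tubules (GT) whose complement
# inside the GA is storage tissue (ST). Because ST is defined as GA minus
# the tubules, GT union ST equals the GA region exactly and the true indices
# are mask ratios by construction.

#' Default trichrome-like class palette
#'
#' Mean RGB and per-channel standard deviation for the four colour classes of
#' a Prenant-Gabe-trichrome-like section: white background, pale-pink
#' connective tissue, pink-orange storage tissue, blue-violet tubules. The
#' classes are separable both in HSI intensity and in CIELAB L*/a*, which is
#' what the threshold segmentation exploits.
#'
#' @return Named list of lists with elements `mean` (RGB triple) and `sd`
#'   (per-channel sd).
#' @export
default_palette <- function() {
  list(
    background = list(mean = c(245, 245, 245), sd = c(3, 3, 3)),
    connective = list(mean = c(230, 180, 190), sd = c(4, 4, 4)),
    storage    = list(mean = c(235, 160, 140), sd = c(4, 4, 4)),
    tubule     = list(mean = c(120, 90, 160),  sd = c(4, 4, 4))
  )
}

#' Specify a synthetic gonad-section phantom
#'
#' @param height_px,width_px Frame size in pixels.
#' @param microns_per_pixel Physical pixel size (default 0.25, emulating the
#'   native 20x scan; a by-8 downsampled phantom would use 2).
#' @param n_tubules Number of elliptical tubules to place.
#' @param tubule_semi_axis_um Length-2 numeric `(meanlog, sdlog)` of the
#'   log-normal distribution of the tubule minor semi-axis, in microns.
#' @param aspect_ratio_range Length-2 numeric, both `>= 1`: uniform range of
#'   the major/minor axis ratio.
#' @param st_fraction Target storage-tissue share of the tissue blob, in
#'   `[0, 1)`. With `st_fraction = 0` no storage region is drawn and the
#'   gonadal area is the tubules alone.
#' @param tissue_fraction Tissue blob share of the frame, in `(0, 1]`;
#'   `1` fills the whole frame. Requests above ~0.93 are met by clipping the
#'   blob to the frame, so the realised fraction can fall slightly short.
#' @param class_palette Palette as returned by [default_palette()].
#' @param tubule_margin_px Minimum clearance kept between placed tubules, in
#'   pixels (default 3; raise it to generate clearly individualized,
#'   well-separated tubules that survive morphological closing unmerged).
#' @param noise_sd Additional independent per-channel Gaussian noise sd.
#' @param seed Integer seed; phantoms are bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height_px = 512, width_px = 512,
                         microns_per_pixel = 0.25,
                         n_tubules = 12,
                         tubule_semi_axis_um = c(log(6), 0.12),
                         aspect_ratio_range = c(1, 1.3),
                         st_fraction = 0.15,
                         tissue_fraction = 0.75,
                         class_palette = default_palette(),
                         tubule_margin_px = 3,
                         noise_sd = 5,
                         seed = 1) {
  stopifnot(
    height_px >= 1, width_px >= 1, microns_per_pixel > 0,
    n_tubules >= 0, length(tubule_semi_axis_um) == 2,
    length(aspect_ratio_range) == 2
  )
  if (aspect_ratio_range[1] < 1 ||
      aspect_ratio_range[1] > aspect_ratio_range[2]) {
    abort("`aspect_ratio_range` must satisfy 1 <= lo <= hi.")
  }
  if (st_fraction < 0 || st_fraction >= 1) {
    abort("`st_fraction` must lie in [0, 1).")
  }
  if (tissue_fraction <= 0 || tissue_fraction > 1) {
    abort("`tissue_fraction` must lie in (0, 1].")
  }
  need <- c("background", "connective", "storage", "tubule")
  if (!all(need %in% names(class_palette))) {
    abort("`class_palette` must name background, connective, storage, tubule.")
  }
  for (cl in need) {
    m <- class_palette[[cl]]$mean
    if (length(m) != 3 || any(m < 0) || any(m > 255)) {
      abort(sprintf("Palette means for '%s' must be RGB triples in [0, 255].", cl))
    }
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (tubule_margin_px < 0) abort("`tubule_margin_px` must be non-negative.")
  structure(
    list(
      height_px = as.integer(height_px), width_px = as.integer(width_px),
      microns_per_pixel = microns_per_pixel,
      n_tubules = as.integer(n_tubules),
      tubule_semi_axis_um = tubule_semi_axis_um,
      aspect_ratio_range = aspect_ratio_range,
      st_fraction = st_fraction, tissue_fraction = tissue_fraction,
      class_palette = class_palette,
      tubule_margin_px = tubule_margin_px, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Render a phantom and its ground truth
#'
#' Generates the tissue blob, places `n_tubules` pairwise non-overlapping
#' ellipses fully inside the gonadal area by rejection sampling (1000
#' attempts per tubule, largest first), fills the remaining gonadal area with
#' storage tissue, and colours every class by sampling its palette plus white
#' noise. The returned truth masks match the rendered geometry exactly and
#' the true indices are computed from the masks, so they hold by
#' construction. Deterministic for a fixed spec (including seed).
#'
#' @param spec A [phantom_spec].
#' @return List with elements `image` (an [rgb_image]) and `truth` (class
#'   `phantom_truth`: `whole_mask`, `gt_mask`, `st_mask`, `tubule_params`
#'   tibble, `true_gti`, `true_tai`, `true_n_tubules`,
#'   `true_mean_tubule_area_um2`).
#' @examples
#' ph <- generate_phantom(phantom_spec(height_px = 128, width_px = 128,
#'                                     n_tubules = 3, seed = 7))
#' ph$truth$true_n_tubules
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height_px; w <- spec$width_px
  withr::with_seed(spec$seed, {
    whole <- blob_mask(h, w, spec$tissue_fraction)
    whole_area <- sum(whole)

    # Tubule sizes (px) sampled before placement so the GA area can be set to
    # st_fraction * blob + total tubule area.
    n <- spec$n_tubules
    minor_px <- numeric(0); major_px <- numeric(0); angle <- numeric(0)
    if (n > 0) {
      minor_um <- stats::rlnorm(n, spec$tubule_semi_axis_um[1],
                                spec$tubule_semi_axis_um[2])
      aspect <- runif(n, spec$aspect_ratio_range[1], spec$aspect_ratio_range[2])
      minor_px <- minor_um / spec$microns_per_pixel
      major_px <- minor_px * aspect
      angle <- runif(n, 0, pi)
    }

    ga <- NULL
    if (spec$st_fraction > 0) {
      ga_area <- spec$st_fraction * whole_area + sum(pi * major_px * minor_px)
      if (ga_area > 0.97 * whole_area) {
        abort("st_fraction plus the sampled tubule load exceed the tissue blob.")
      }
      ga <- scaled_blob(h, w, spec$tissue_fraction, ga_area / whole_area)
      ga <- ga & whole
    }
    domain <- if (is.null(ga)) whole else ga
    if (n > 0 && !any(domain)) abort("Tissue blob is empty; nothing to place tubules in.")
    dr <- range(row(domain)[domain]); dc <- range(col(domain)[domain])

    ord <- if (n > 0) order(major_px, decreasing = TRUE) else integer(0)
    placed <- list()
    cys <- numeric(0); cxs <- numeric(0); radii <- numeric(0)
    for (i in ord) {
      a <- major_px[i]; b <- minor_px[i]
      ok <- FALSE
      for (try in seq_len(1000L)) {
        cy <- runif(1, dr[1], dr[2])
        cx <- runif(1, dc[1], dc[2])
        if (length(radii) &&
            any((cys - cy)^2 + (cxs - cx)^2 <= (radii + a + spec$tubule_margin_px)^2)) next
        idx <- ellipse_indices(h, w, cy, cx, a, b, angle[i])
        if (!length(idx) || !all(domain[idx])) next
        placed[[length(placed) + 1L]] <-
          list(i = i, cy = cy, cx = cx, idx = idx)
        cys <- c(cys, cy); cxs <- c(cxs, cx); radii <- c(radii, a)
        ok <- TRUE
        break
      }
      if (!ok) {
        abort(sprintf(
          "Could not place tubule %d (semi-major %.1f px) after 1000 attempts; reduce n_tubules, tubule size or st_fraction.",
          i, a))
      }
    }

    gt <- matrix(FALSE, h, w)
    areas_px <- integer(length(placed))
    for (k in seq_along(placed)) {
      gt[placed[[k]]$idx] <- TRUE
      areas_px[k] <- length(placed[[k]]$idx)
    }
    st <- if (is.null(ga)) matrix(FALSE, h, w) else (ga & !gt)

    # Class map: 0 background, 1 connective, 2 storage, 3 tubule.
    cls <- matrix(0L, h, w)
    cls[whole] <- 1L
    cls[st] <- 2L
    cls[gt] <- 3L

    pal <- spec$class_palette[c("background", "connective", "storage", "tubule")]
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      mu <- vapply(pal, function(p) p$mean[ch], numeric(1))[cls + 1L]
      sd_cl <- vapply(pal, function(p) p$sd[ch], numeric(1))[cls + 1L]
      total_sd <- sqrt(sd_cl^2 + spec$noise_sd^2)
      v <- mu + rnorm(h * w) * total_sd
      px[, , ch] <- floor(pmin(pmax(v, 0), 255) + 0.5)
    }

    params <- tibble(
      center_row = vapply(placed, `[[`, numeric(1), "cy"),
      center_col = vapply(placed, `[[`, numeric(1), "cx"),
      semi_major_px = major_px[vapply(placed, `[[`, integer(1), "i")],
      semi_minor_px = minor_px[vapply(placed, `[[`, integer(1), "i")],
      angle_rad = angle[vapply(placed, `[[`, integer(1), "i")]
    )

    truth <- structure(
      list(
        whole_mask = whole, gt_mask = gt, st_mask = st,
        tubule_params = params,
        true_gti = 100 * sum(gt | st) / whole_area,
        true_tai = 100 * sum(gt) / whole_area,
        true_n_tubules = length(placed),
        true_mean_tubule_area_um2 =
          if (length(areas_px)) mean(areas_px) * spec$microns_per_pixel^2
          else NA_real_
      ),
      class = "phantom_truth"
    )
    list(
      image = rgb_image(px, microns_per_pixel = spec$microns_per_pixel),
      truth = truth
    )
  })
}

# Tissue blob: squircle with a/b = w/h whose raster area targets
# fraction * h * w; fraction 1 is the full frame.
blob_mask <- function(h, w, fraction) {
  if (fraction >= 1) return(matrix(TRUE, h, w))
  b <- sqrt(fraction * h * w * h / (SQUIRCLE_K * w))
  a <- b * w / h
  squircle_mask(h, w, a, b)
}

# Concentric scaled copy of the blob with area = rel * blob area.
scaled_blob <- function(h, w, fraction, rel) {
  if (fraction >= 1) {
    # full-frame blob: use a squircle of the requested relative area
    b <- sqrt(rel * h * w * h / (SQUIRCLE_K * w))
    return(squircle_mask(h, w, b * w / h, b))
  }
  b <- sqrt(fraction * h * w * h / (SQUIRCLE_K * w))
  s <- sqrt(rel)
  squircle_mask(h, w, b * w / h * s, b * s)
}

#' Section metrics straight from ground-truth masks
#'
#' Computes [SectionMetrics][summarize_section()] directly from a phantom's
#' truth masks (gonadal area = GT union ST), bypassing segmentation. Serves
#' as the oracle against which the estimated pipeline output is compared.
#'
#' @param truth A `phantom_truth`.
#' @param microns_per_pixel Pixel size of the truth masks.
#' @return One-row tibble matching the [summarize_section()] schema.
#' @export
truth_metrics <- function(truth, microns_per_pixel) {
  stopifnot(inherits(truth, "phantom_truth"))
  d <- dim(truth$whole_mask)
  if (!identical(d, dim(truth$gt_mask)) || !identical(d, dim(truth$st_mask))) {
    abort("Truth masks must share one shape.")
  }
  whole <- sum(truth$whole_mask)
  ga <- sum(truth$gt_mask | truth$st_mask)
  gtn <- sum(truth$gt_mask)
  stn <- sum(truth$st_mask)
  mpp2 <- microns_per_pixel^2
  tibble(
    whole_area_px = whole, ga_area_px = ga, gt_area_px = gtn, st_area_px = stn,
    whole_area_um2 = whole * mpp2, ga_area_um2 = ga * mpp2,
    gt_area_um2 = gtn * mpp2, st_area_um2 = stn * mpp2,
    gti_percent = compute_gti(ga, whole),
    tai_percent = compute_tai(gtn, whole),
    n_tubules = truth$true_n_tubules,
    mean_area_per_tubule_um2 = truth$true_mean_tubule_area_um2
  )
}

#' Phantom specs for the study's stage and ploidy groups
#'
#' Named presets whose true gonadal-area fraction follows the printed group
#' GTI values: stage 1 — 20% (diploid), 17% (alpha triploid), 10% (beta
#' triploid); stage 3 — 85%, 71%, 23%; stage 0 — 12.5% for every class (the
#' reported range is 10-15% with no class difference). The GT share of the
#' gonadal area is a package choice (no absolute tubule-area value is
#' printed): 0.25 of GA, giving feasible non-overlapping tubule packing at
#' every preset. Stage 2 has no printed index and therefore no preset.
#'
#' @param stage Gametogenetic stage, one of 0, 1, 3.
#' @param ploidy_class One of `"2n"`, `"3n_alpha"`, `"3n_beta"`.
#' @param height_px,width_px Frame size (default 1024).
#' @param seed Integer seed.
#' @param noise_sd Per-channel noise sd (default 10).
#' @return A [phantom_spec] whose expected `true_gti` equals the group value.
#' @export
stage_phantom_spec <- function(stage, ploidy_class = c("2n", "3n_alpha", "3n_beta"),
                               height_px = 1024, width_px = 1024,
                               seed = 1, noise_sd = 10) {
  ploidy_class <- match.arg(ploidy_class)
  key <- paste0("s", stage, "_", ploidy_class)
  gti <- c(
    s0_2n = 12.5, s0_3n_alpha = 12.5, s0_3n_beta = 12.5,
    s1_2n = 20, s1_3n_alpha = 17, s1_3n_beta = 10,
    s3_2n = 85, s3_3n_alpha = 71, s3_3n_beta = 23
  )[key]
  if (is.na(gti)) {
    abort(sprintf("No preset for stage %s / %s (stage 2 has no printed index).",
                  as.character(stage), ploidy_class))
  }
  n_tubules <- c(s0 = 10, s1 = 20, s3 = 40)[paste0("s", stage)]
  if (stage == 0 && ploidy_class != "2n") n_tubules <- 6  # fewer tubules in 3n
  gt_share <- 0.25
  tissue_fraction <- 0.75
  mpp <- 0.25
  blob_px <- tissue_fraction * height_px * width_px
  mean_area_px <- gti / 100 * gt_share * blob_px / n_tubules
  aspect_range <- c(1, 1.3)
  sdlog <- 0.12
  b_px <- sqrt(mean_area_px / (pi * mean(aspect_range)))
  meanlog <- log(b_px * mpp) - sdlog^2
  phantom_spec(
    height_px = height_px, width_px = width_px, microns_per_pixel = mpp,
    n_tubules = n_tubules,
    tubule_semi_axis_um = c(meanlog, sdlog),
    aspect_ratio_range = aspect_range,
    st_fraction = gti / 100 * (1 - gt_share),
    tissue_fraction = tissue_fraction,
    noise_sd = noise_sd, seed = seed
  )
}
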