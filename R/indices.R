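# Reproductive-effort indices. GTI = 100 * GA / whole section,
# TAI = 100 * GT / whole section, where the gonadal area GA is the region
# around the digestive gland containing tubules and storage tissue.

#' Gonadal-area mask from the tissue masks
#'
#' GA is the union of the GT and ST masks followed by a morphological
#' closing (disc, default radius 5 px; 0 disables) that bridges thin
#' interstitial gaps between tubules and storage lobes, intersected with the
#' whole-tissue mask. The closing radius is the explicit knob standing in
#' for how much interstitial connective tissue the gonadal area includes.
#'
#' @param masks A [tissue_masks].
#' @param closing_radius Disc radius in pixels (default 5).
#' @return Logical GA mask.
#' @export
gonadal_area <- function(masks, closing_radius = 5) {
  stopifnot(inherits(masks, "tissue_masks"))
  ga <- masks$gt | masks$st
  if (any(ga) && closing_radius > 0) {
    ga <- close_and_fill(ga, radius = closing_radius, fill = FALSE)
  }
  ga & masks$whole
}

#' Gonadal Tubule Index
#'
#' `GTI = 100 * GA / whole`, the percentage of the animal cross section
#' occupied by the gonadal area.
#'
#' @param ga_area,whole_area Areas in any common unit; `whole_area > 0` and
#'   `ga_area <= whole_area`.
#' @return GTI in percent.
#' @export
compute_gti <- function(ga_area, whole_area) {
  if (any(whole_area <= 0)) abort("`whole_area` must be positive.")
  if (any(ga_area < 0) || any(ga_area > whole_area)) {
    abort("Need 0 <= ga_area <= whole_area.")
  }
  100 * ga_area / whole_area
}

#' Tubule Area Index
#'
#' `TAI = 100 * GT / whole`, the percentage of the animal cross section
#' occupied by the gonadal tubules proper. Always `<= GTI` since GT is part
#' of the gonadal area.
#'
#' @inheritParams compute_gti
#' @param gt_area Tubule area.
#' @return TAI in percent.
#' @export
compute_tai <- function(gt_area, whole_area) {
  compute_gti(gt_area, whole_area)
}

#' Per-section metrics from masks and tubule records
#'
#' Combines the three tissue masks and the per-tubule morphometry into one
#' row of section metrics: areas (px and um2), GTI, TAI, tubule count and
#' mean area per tubule. With `circular_only = TRUE` (the convention for the
#' stage 0-1 tubule analysis) the count and mean area cover only tubules
#' passing [filter_circular()]; the area indices are mask ratios and are
#' never affected by the filter.
#'
#' @param masks A [tissue_masks].
#' @param records Tibble from [measure_tubules()] measured on `masks$gt`.
#' @param microns_per_pixel Pixel size in microns.
#' @param metadata Named list with any of `animal_id`, `stage`,
#'   `ploidy_class`.
#' @param circular_only Count only tubules with `K < k_max`?
#' @param k_max Gravelius threshold (default 1.7).
#' @param ga_closing_radius Passed to [gonadal_area()].
#' @return One-row tibble of section metrics.
#' @export
summarize_section <- function(masks, records, microns_per_pixel = 2,
                              metadata = list(), circular_only = TRUE,
                              k_max = 1.7, ga_closing_radius = 5) {
  stopifnot(inherits(masks, "tissue_masks"), is.data.frame(records))
  ga <- gonadal_area(masks, closing_radius = ga_closing_radius)
  whole_px <- sum(masks$whole)
  ga_px <- sum(ga)
  gt_px <- sum(masks$gt)
  st_px <- sum(masks$st)
  counted <- if (circular_only) filter_circular(records, k_max) else records
  mpp2 <- microns_per_pixel^2
  tibble(
    animal_id = metadata$animal_id %||% NA_character_,
    stage = metadata$stage %||% NA_integer_,
    ploidy_class = metadata$ploidy_class %||% NA_character_,
    whole_area_px = whole_px, ga_area_px = ga_px,
    gt_area_px = gt_px, st_area_px = st_px,
    whole_area_um2 = whole_px * mpp2, ga_area_um2 = ga_px * mpp2,
    gt_area_um2 = gt_px * mpp2, st_area_um2 = st_px * mpp2,
    gti_percent = compute_gti(ga_px, whole_px),
    tai_percent = compute_tai(gt_px, whole_px),
    n_tubules = nrow(counted),
    mean_area_per_tubule_um2 =
      if (nrow(counted) > 0) mean(counted$area_um2) else NA_real_
  )
}
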