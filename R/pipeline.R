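# Section- and cohort-level orchestration: image -> downsample -> colour
# normalisation -> three-tissue segmentation -> tubule morphometry ->
# section metrics -> cohort statistics, with every threshold logged.

#' Pipeline configuration
#'
#' All tunable parameters of the section pipeline in one list. Defaults
#' follow the analysis conventions for 20x scans: native 0.25 um/px,
#' downsampling by 8, automatic thresholds, Gravelius filter at
#' K < 1.7 applied to tubule counts only.
#'
#' @param microns_per_pixel Pixel size of the input images (pre-downsample).
#' @param downsample_factor Block-averaging factor applied on load.
#' @param color_reference Optional [color_reference()]; `NULL` skips
#'   normalisation.
#' @param whole_threshold,l_threshold,a_threshold Fixed thresholds; `NULL`
#'   uses the automatic method (see [segment_whole()], [segment_gt()]).
#' @param whole_method Automatic method for the whole-tissue intensity cut:
#'   `"otsu3"` (default), `"otsu"` or `"isodata"`.
#' @param threshold_method Automatic method for the L*/a* tubule thresholds:
#'   `"otsu"` (default) or `"isodata"`.
#' @param min_component_px Minimum whole-tissue component size.
#' @param min_area_px Minimum tubule size for [label_tubules()].
#' @param k_max Gravelius threshold for [filter_circular()].
#' @param circular_only Count only circular tubules in section metrics?
#' @param ga_closing_radius Closing radius for [gonadal_area()].
#' @param st_model Optional trained [fit_st_classifier()] model; `NULL`
#'   leaves the ST mask empty (logged).
#' @param drop_border Drop tubules touching the image border from the
#'   records (default `FALSE`; they are flagged either way).
#' @param seed Integer seed for any stochastic step.
#' @return A list of class `effort_config`.
#' @export
pipeline_config <- function(microns_per_pixel = 0.25, downsample_factor = 8,
                            color_reference = NULL, whole_threshold = NULL,
                            l_threshold = NULL, a_threshold = NULL,
                            whole_method = c("otsu3", "otsu", "isodata"),
                            threshold_method = c("otsu", "isodata"),
                            min_component_px = 64, min_area_px = 30,
                            k_max = 1.7, circular_only = TRUE,
                            ga_closing_radius = 5, st_model = NULL,
                            drop_border = FALSE, seed = 1) {
  structure(
    list(
      microns_per_pixel = microns_per_pixel,
      downsample_factor = downsample_factor,
      color_reference = color_reference,
      whole_threshold = whole_threshold,
      l_threshold = l_threshold, a_threshold = a_threshold,
      whole_method = match.arg(whole_method),
      threshold_method = match.arg(threshold_method),
      min_component_px = min_component_px, min_area_px = min_area_px,
      k_max = k_max, circular_only = circular_only,
      ga_closing_radius = ga_closing_radius, st_model = st_model,
      drop_border = drop_border, seed = as.integer(seed)
    ),
    class = "effort_config"
  )
}

#' Run the full pipeline on one section
#'
#' Executes downsample -> colour normalisation -> whole/GT/ST segmentation
#' -> tubule labeling, measurement and Gravelius filtering -> section
#' metrics. Accepts an [rgb_image] or a path readable by
#' [read_rgb_image()]. Thresholds actually used, discarded-object counts
#' and skipped stages are recorded in the returned log; with `out_dir` set,
#' masks (PNG), the per-tubule table (CSV), the metrics (JSON) and the log
#' (JSON) are written there.
#'
#' @param image An [rgb_image] or an image file path.
#' @param config An [pipeline_config()] list.
#' @param metadata Named list: `animal_id`, `stage`, `ploidy_class`.
#' @param exclusion Optional logical matrix (at post-downsample size) of
#'   pixels to exclude from the whole-tissue mask.
#' @param out_dir Optional output directory.
#' @return List of class `section_result`: `metrics` (one-row tibble),
#'   `tubules` (tibble), `masks` ([tissue_masks]), `image` (processed
#'   [rgb_image]), `log` (list).
#' @export
run_section <- function(image, config = pipeline_config(),
                        metadata = list(), exclusion = NULL, out_dir = NULL) {
  log <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Section pipeline failed at stage '%s': %s",
                    name, conditionMessage(e)))
    })
  }
  if (is.character(image)) {
    image <- step("read", read_rgb_image(image, config$microns_per_pixel))
  }
  stopifnot(inherits(image, "rgb_image"))
  img <- step("downsample", downsample(image, config$downsample_factor))
  log$downsample_factor <- config$downsample_factor
  log$microns_per_pixel <- img$microns_per_pixel
  if (!is.null(config$color_reference)) {
    img <- step("color_normalize",
                color_normalize(img, config$color_reference))
    log$color_normalized <- TRUE
  } else {
    log$color_normalized <- FALSE
  }
  whole <- step("segment_whole", segment_whole(
    img, exclusion = exclusion, threshold = config$whole_threshold,
    min_component_px = config$min_component_px,
    method = config$whole_method
  ))
  log$whole <- attr(whole, "threshold_log")
  gt <- step("segment_gt", segment_gt(
    img, whole, l_threshold = config$l_threshold,
    a_threshold = config$a_threshold, method = config$threshold_method
  ))
  log$gt <- attr(gt, "threshold_log")
  if (is.null(config$st_model)) {
    st <- matrix(FALSE, nrow(whole), ncol(whole))
    log$st <- list(skipped = "no st_model in config; ST mask left empty")
  } else {
    st <- step("segment_st", segment_st(img, whole, gt, config$st_model))
    log$st <- list(skipped = FALSE, classifier_seed = config$st_model$seed)
  }
  masks <- tissue_masks(whole, gt, st, threshold_log = log)
  labels <- step("label_tubules", label_tubules(masks$gt, config$min_area_px))
  log$tubules <- list(
    n_labeled = attr(labels, "n_labels"),
    n_discarded_small = attr(labels, "n_discarded"),
    px_discarded = attr(labels, "px_discarded")
  )
  records <- step("measure", measure_tubules(labels, img$microns_per_pixel))
  if (config$drop_border) {
    records <- dplyr::filter(records, !.data$touches_border)
  }
  metrics <- step("summarize", summarize_section(
    masks, records, microns_per_pixel = img$microns_per_pixel,
    metadata = metadata, circular_only = config$circular_only,
    k_max = config$k_max, ga_closing_radius = config$ga_closing_radius
  ))
  res <- structure(
    list(metrics = metrics, tubules = records, masks = masks,
         image = img, log = log),
    class = "section_result"
  )
  if (!is.null(out_dir)) write_section_result(res, out_dir, metadata)
  res
}

write_section_result <- function(res, out_dir, metadata = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- metadata$animal_id %||% "section"
  write_mask_png(res$masks$whole, file.path(out_dir, paste0(id, "_whole.png")))
  write_mask_png(res$masks$gt, file.path(out_dir, paste0(id, "_gt.png")))
  write_mask_png(res$masks$st, file.path(out_dir, paste0(id, "_st.png")))
  utils::write.csv(res$tubules, file.path(out_dir, paste0(id, "_tubules.csv")),
                   row.names = FALSE)
  jsonlite::write_json(as.list(res$metrics),
                       file.path(out_dir, paste0(id, "_metrics.json")),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$log, file.path(out_dir, paste0(id, "_log.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.section_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<section_result> GTI %.1f%%, TAI %.1f%%, %d tubule(s)%s\n",
    m$gti_percent, m$tai_percent, m$n_tubules,
    if (is.na(m$mean_area_per_tubule_um2)) ""
    else sprintf(", mean area %.0f um2", m$mean_area_per_tubule_um2)
  ))
  invisible(x)
}

#' Run the pipeline over a cohort manifest
#'
#' The manifest maps images to animals: columns `image_path` (or `image`, a
#' list-column of [rgb_image]s), `animal_id`, `ploidy_class` (one of `2n`,
#' `3n_alpha`, `3n_beta`, `3n_undiff`), `stage` (0-3), optional
#' `exclusion_mask_path`. Failed sections are skipped and counted; the
#' result carries the per-section metrics, group means with SEM, and all
#' pairwise within-stage t-tests for GTI, TAI, tubule count and mean tubule
#' area.
#'
#' @param manifest Data frame as above.
#' @param config An [pipeline_config()].
#' @param out_dir Optional output directory for per-section artefacts and
#'   cohort CSV tables.
#' @return List of class `cohort_result`: `sections`, `summary`,
#'   `comparisons`, `failures` (tibble), `n_failed`.
#' @export
run_cohort <- function(manifest, config = pipeline_config(), out_dir = NULL) {
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0) abort("Manifest is empty.")
  need <- c("animal_id", "ploidy_class", "stage")
  if (!all(need %in% names(manifest))) {
    abort("Manifest needs columns animal_id, ploidy_class, stage.")
  }
  if (!all(manifest$stage %in% 0:3)) abort("`stage` must be in 0..3.")
  ok_classes <- c("2n", "3n_alpha", "3n_beta", "3n_undiff")
  if (!all(manifest$ploidy_class %in% ok_classes)) {
    abort(sprintf("`ploidy_class` must be one of %s.",
                  paste(ok_classes, collapse = ", ")))
  }
  results <- vector("list", nrow(manifest))
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    meta <- list(animal_id = as.character(manifest$animal_id[i]),
                 stage = as.integer(manifest$stage[i]),
                 ploidy_class = manifest$ploidy_class[i])
    img <- if ("image" %in% names(manifest)) manifest$image[[i]]
           else manifest$image_path[i]
    excl <- NULL
    if ("exclusion_mask_path" %in% names(manifest) &&
        !is.na(manifest$exclusion_mask_path[i])) {
      excl <- read_mask_png(manifest$exclusion_mask_path[i])
    }
    sec <- tryCatch(
      run_section(img, config, metadata = meta, exclusion = excl,
                  out_dir = out_dir),
      error = function(e) {
        failures[[length(failures) + 1L]] <<-
          tibble(animal_id = meta$animal_id, error = conditionMessage(e))
        NULL
      }
    )
    results[i] <- list(sec)  # [[<- NULL would drop the slot
  }
  done <- !vapply(results, is.null, logical(1))
  if (!any(done)) abort("Every section in the manifest failed.")
  sections <- dplyr::bind_rows(purrr::map(results[done], "metrics"))
  metrics <- c("gti_percent", "tai_percent", "n_tubules",
               "mean_area_per_tubule_um2")
  summary <- purrr::map_dfr(metrics, function(v) {
    dplyr::mutate(group_summary(sections, v), metric = v, .before = 1)
  })
  comparisons <- dplyr::bind_rows(
    purrr::map(metrics, ~ compare_groups(sections, .x))
  )
  out <- structure(
    list(sections = sections, summary = summary, comparisons = comparisons,
         failures = dplyr::bind_rows(failures),
         n_failed = sum(!done)),
    class = "cohort_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sections, file.path(out_dir, "cohort_sections.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "cohort_comparisons.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "<cohort_result> %d section(s), %d failed; %d comparison row(s)\n",
    nrow(x$sections), x$n_failed, nrow(x$comparisons)
  ))
  invisible(x)
}
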