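# Group statistics in the style of the study: means with SEM, pooled
# Student's t-tests between ploidy groups within each gametogenetic stage,
# and the multi-level significance-star mapping used on the figures.

#' Mean and standard error of the mean
#'
#' SEM uses the sample standard deviation (n - 1 denominator) over sqrt(n).
#' A single value has no defined SEM and is an error.
#'
#' @param values Numeric vector, `n >= 2`, no missing entries.
#' @return One-row tibble with `mean`, `sem`, `n`.
#' @examples
#' mean_sem(c(1, 2, 3)) # mean 2, sem 0.5774
#' @export
mean_sem <- function(values) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (anyNA(values)) abort("`values` must have no missing entries.")
  if (length(values) == 1) {
    abort("SEM is undefined for a single value (n = 1).")
  }
  tibble(mean = mean(values), sem = sd(values) / sqrt(length(values)),
         n = length(values))
}

#' Two-sample Student's t-test between groups
#'
#' Classic pooled-variance Student's t (two-sided) as used for the
#' between-ploidy comparisons; Welch's correction is available via
#' `var_equal = FALSE`. When both groups have zero variance the statistic is
#' degenerate: the result is flagged, with `p = 1` for equal means and
#' `p = 0` otherwise.
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @param var_equal Pool the variances (default `TRUE`)?
#' @return An object of class `effort_ttest`; see [tidy()] for the tabular
#'   form.
#' @examples
#' tt <- t_test_groups(c(1, 2, 3), c(2, 3, 4))
#' tidy(tt)
#' @export
t_test_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least two values.")
  }
  if (anyNA(a) || anyNA(b)) abort("Groups must have no missing entries.")
  degenerate <- var(a) == 0 && var(b) == 0
  if (degenerate) {
    equal <- mean(a) == mean(b)
    res <- list(
      t_statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
      degrees_of_freedom = length(a) + length(b) - 2,
      p_value = if (equal) 1 else 0
    )
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    res <- list(
      t_statistic = unname(tt$statistic),
      degrees_of_freedom = unname(tt$parameter),
      p_value = tt$p.value
    )
  }
  structure(
    list(
      mean_a = mean(a), mean_b = mean(b),
      sem_a = sd(a) / sqrt(length(a)), sem_b = sd(b) / sqrt(length(b)),
      n_a = length(a), n_b = length(b),
      t_statistic = res$t_statistic,
      degrees_of_freedom = res$degrees_of_freedom,
      p_value = res$p_value,
      stars = significance_stars(res$p_value),
      degenerate_flag = degenerate,
      var_equal = var_equal
    ),
    class = "effort_ttest"
  )
}

#' @export
print.effort_ttest <- function(x, ...) {
  cat(sprintf(
    "%s t-test: %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d)\n  t = %.4g, df = %.4g, p = %.4g %s%s\n",
    if (x$var_equal) "Pooled Student's" else "Welch's",
    x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
    x$t_statistic, x$degrees_of_freedom, x$p_value, x$stars,
    if (x$degenerate_flag) " [degenerate: zero variance]" else ""
  ))
  invisible(x)
}

#' @rdname t_test_groups
#' @param x An `effort_ttest`.
#' @param ... Unused.
#' @method tidy effort_ttest
#' @export
tidy.effort_ttest <- function(x, ...) {
  tibble(
    mean_a = x$mean_a, mean_b = x$mean_b, sem_a = x$sem_a, sem_b = x$sem_b,
    n_a = x$n_a, n_b = x$n_b, t_statistic = x$t_statistic,
    degrees_of_freedom = x$degrees_of_freedom, p_value = x$p_value,
    stars = x$stars, degenerate_flag = x$degenerate_flag
  )
}

#' @rdname t_test_groups
#' @method glance effort_ttest
#' @export
glance.effort_ttest <- function(x, ...) {
  tibble(t_statistic = x$t_statistic,
         degrees_of_freedom = x$degrees_of_freedom,
         p_value = x$p_value, stars = x$stars)
}

#' Significance stars
#'
#' The figure-legend mapping: `****` for p < 0.0001, `***` for p < 0.0005,
#' `**` for p < 0.001, `*` for p < 0.05, otherwise `"ns"`. Vectorised.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of star strings.
#' @examples
#' significance_stars(c(0.00005, 0.0007, 0.2))
#' @export
significance_stars <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  dplyr::case_when(
    p < 0.0001 ~ "****",
    p < 0.0005 ~ "***",
    p < 0.001 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Group means with SEM for a metrics table
#'
#' Convenience summary of per-animal metrics by stage and ploidy class,
#' matching the bars-with-SEM presentation of the study's figures.
#'
#' @param data Data frame of per-section/per-animal metrics.
#' @param value Column name (string) of the metric.
#' @param group_cols Character vector of grouping columns.
#' @return Tibble with `mean`, `sem`, `n` per group (SEM `NA` when n = 1).
#' @export
group_summary <- function(data, value,
                          group_cols = c("stage", "ploidy_class")) {
  stopifnot(is.data.frame(data), value %in% names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      mean = mean(.data[[value]], na.rm = TRUE),
      sem = if (dplyr::n() > 1) sd(.data[[value]], na.rm = TRUE) / sqrt(dplyr::n())
            else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Pairwise within-stage group comparisons
#'
#' Runs [t_test_groups()] for every pair of ploidy classes within each
#' stage, for one metric, and returns a tidy comparison table with stars.
#' Pairs where a group has fewer than two values are skipped.
#'
#' @param data Per-animal metrics data frame with `stage` and `ploidy_class`.
#' @param value Metric column name (string).
#' @param var_equal Passed to [t_test_groups()].
#' @return Tibble with one row per (stage, group pair).
#' @export
compare_groups <- function(data, value, var_equal = TRUE) {
  stopifnot(is.data.frame(data), value %in% names(data),
            all(c("stage", "ploidy_class") %in% names(data)))
  out <- list()
  for (st in sort(unique(data$stage))) {
    sub <- data[data$stage == st & !is.na(data[[value]]), , drop = FALSE]
    groups <- sort(unique(sub$ploidy_class))
    if (length(groups) < 2) next
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        va <- sub[[value]][sub$ploidy_class == groups[i]]
        vb <- sub[[value]][sub$ploidy_class == groups[j]]
        if (length(va) < 2 || length(vb) < 2) next
        row <- tidy(t_test_groups(va, vb, var_equal = var_equal))
        row <- dplyr::bind_cols(
          tibble(stage = st, metric = value,
                 group_a = groups[i], group_b = groups[j]),
          row
        )
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    return(tibble(stage = integer(0), metric = character(0),
                  group_a = character(0), group_b = character(0)))
  }
  dplyr::bind_rows(out)
}
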