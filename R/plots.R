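# ggplot2 views of the result objects.

#' Plot a section result as image + mask overlay
#'
#' Shows the processed section with the segmented tissue outlines: whole
#' tissue, gonadal tubules and storage tissue as translucent fills.
#'
#' @param object A `section_result` from [run_section()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot section_result
#' @export
autoplot.section_result <- function(object, ...) {
  img <- object$image
  d <- dim(img$pixels)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(
    as.vector(img$pixels[, , 1]) / 255,
    as.vector(img$pixels[, , 2]) / 255,
    as.vector(img$pixels[, , 3]) / 255
  )[(df$col - 1L) * d[1] + df$row]
  cls <- dplyr::case_when(
    as.vector(object$masks$gt)[(df$col - 1L) * d[1] + df$row] ~ "GT",
    as.vector(object$masks$st)[(df$col - 1L) * d[1] + df$row] ~ "ST",
    as.vector(object$masks$whole)[(df$col - 1L) * d[1] + df$row] ~ "tissue",
    TRUE ~ NA_character_
  )
  df$tissue <- cls
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_raster(
      data = dplyr::filter(df, !is.na(.data$tissue)),
      ggplot2::aes(alpha = .data$tissue), fill = "blue"
    ) +
    ggplot2::scale_alpha_manual(
      values = c(GT = 0.35, ST = 0.15, tissue = 0.03), na.value = 0
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(alpha = "mask", x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot cohort group means with SEM bars and stars
#'
#' Bar chart of group means (per stage and ploidy class) with SEM error
#' bars for one metric, the presentation used for reproductive-effort
#' indices.
#'
#' @param object A `cohort_result` from [run_cohort()].
#' @param metric Metric column to show (default `"gti_percent"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_result
#' @export
autoplot.cohort_result <- function(object, metric = "gti_percent", ...) {
  sm <- dplyr::filter(object$summary, .data$metric == !!metric)
  ggplot2::ggplot(sm, ggplot2::aes(
    x = factor(.data$stage), y = .data$mean, fill = .data$ploidy_class
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.25
    ) +
    ggplot2::labs(x = "gametogenetic stage", y = metric,
                  fill = "ploidy") +
    ggplot2::theme_minimal()
}

#' Quick look at a phantom image
#'
#' @param image An [rgb_image].
#' @return A ggplot raster of the image.
#' @export
plot_image <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image$pixels)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  lin <- (df$col - 1L) * d[1] + df$row
  df$fill <- grDevices::rgb(
    as.vector(image$pixels[, , 1])[lin] / 255,
    as.vector(image$pixels[, , 2])[lin] / 255,
    as.vector(image$pixels[, , 3])[lin] / 255
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
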