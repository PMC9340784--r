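# qPCR relative expression by cycle-threshold deviation from the
# housekeeping gene (EF1-alpha), and mitosis phase-frequency tables.

#' Relative expression from Ct deviation
#'
#' `2^-(Ct_target - Ct_reference)`: expression relative to the housekeeping
#' gene, assuming perfect doubling per cycle. One extra cycle halves the
#' relative level. Vectorised.
#'
#' @param ct_target,ct_reference Finite cycle-threshold values.
#' @return Positive relative expression level(s).
#' @examples
#' relative_expression(21, 20) # 0.5
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    abort("Ct values must be finite.")
  }
  2^(-(ct_target - ct_reference))
}

#' Relative-expression table from a Ct table
#'
#' Joins each target-gene Ct to the reference-gene Ct of the same sample and
#' computes [relative_expression()]. The study's reference gene is EF1-alpha;
#' its panel of targets is CDC20, MAD2L1, MIS12, RAD21 and BUB3 (mitotic
#' spindle-checkpoint and cohesin components).
#'
#' @param ct Data frame with columns `sample_id`, `gene`, `ct`.
#' @param reference_gene Reference gene name as it appears in `gene`
#'   (default `"EF1a"`).
#' @return Tibble with `sample_id`, `target_gene`, `ct_target`,
#'   `ct_reference`, `relative_expression`.
#' @export
expression_table <- function(ct, reference_gene = "EF1a") {
  stopifnot(is.data.frame(ct),
            all(c("sample_id", "gene", "ct") %in% names(ct)))
  ref <- ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select(sample_id = "sample_id", ct_reference = "ct")
  if (nrow(ref) == 0) {
    abort(sprintf("Reference gene '%s' not found in the Ct table.",
                  reference_gene))
  }
  targets <- dplyr::filter(ct, .data$gene != reference_gene)
  missing <- setdiff(unique(targets$sample_id), ref$sample_id)
  if (length(missing)) {
    abort(sprintf("No reference Ct for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  targets |>
    dplyr::inner_join(ref, by = "sample_id") |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      target_gene = .data$gene,
      ct_target = .data$ct,
      ct_reference = .data$ct_reference,
      relative_expression =
        relative_expression(.data$ct, .data$ct_reference)
    ) |>
    as_tibble()
}

#' Mitosis phase order used for frequency tables
#' @export
mitosis_phases <- function() {
  c("G2", "early_prophase", "late_prophase", "prometaphase_metaphase",
    "anaphase", "telophase")
}

#' Relative frequency of mitosis figures
#'
#' Converts per-phase counts of mitotic figures (classified from H3S10p
#' labeling) into percentages of the total; the percentages sum to 100.
#'
#' @param counts Named non-negative numeric vector of per-phase counts, or a
#'   data frame with columns `phase` and `count`. Total must be positive.
#' @return Tibble with `phase`, `count`, `percent`.
#' @examples
#' phase_frequencies(c(late_prophase = 63, prometaphase_metaphase = 30,
#'                     anaphase = 7))
#' @export
phase_frequencies <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("phase", "count") %in% names(counts)))
    phase <- as.character(counts$phase)
    n <- counts$count
  } else {
    if (is.null(names(counts))) abort("`counts` must be named by phase.")
    phase <- names(counts)
    n <- as.numeric(counts)
  }
  if (any(n < 0)) abort("Counts must be non-negative.")
  total <- sum(n)
  if (total <= 0) abort("Total count must be positive.")
  tibble(phase = phase, count = n, percent = 100 * n / total)
}
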