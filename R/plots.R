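#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style view of one assay's comparisons
#'
#' Odds ratio (log2) against BH q-value (-log10) for every gene in every
#' comparison of a call set, colouring genes in the all-comparison
#' intersection. Infinite odds ratios are pinned to the panel edge.
#'
#' @param object A `target_call_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.target_call_set <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(!is.na(.data$odds_ratio))
  finite_or <- df$odds_ratio[is.finite(df$odds_ratio) & df$odds_ratio > 0]
  cap <- if (length(finite_or)) max(finite_or) * 2 else 4
  df <- df |>
    dplyr::mutate(
      or_capped = pmin(pmax(.data$odds_ratio, 1 / cap), cap),
      neglog_q = -log10(pmax(.data$q_value, 1e-300))
    )
  ggplot2::ggplot(df, ggplot2::aes(log2(.data$or_capped), .data$neglog_q,
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = log2(object$thresholds$or_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$thresholds$q_max),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison_id)) +
    ggplot2::labs(
      x = "log2 odds ratio (control / mimic)",
      y = "-log10 BH q-value",
      colour = "called",
      title = paste(object$assay, object$cell_line, sep = " / ")
    ) +
    ggplot2::theme_minimal()
}

#' Bar view of a directional-bias result
#'
#' Up/down sample counts with the Clopper-Pearson interval on the
#' down-proportion.
#'
#' @param object A `directional_bias`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.directional_bias <- function(object, ...) {
  df <- tibble::tibble(
    direction = factor(c("up", "down"), levels = c("up", "down")),
    n = c(object$n_up, object$n_down)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$direction, .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      y = "samples",
      title = sprintf("down-proportion %.2f [%.2f, %.2f], p = %.3g",
                      object$proportion_down, object$ci_low,
                      object$ci_high, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Thresholded change counts per subtype
#'
#' Up/down gene-sample event counts per |z| threshold, faceted by
#' stratum.
#'
#' @param object A `threshold_counts` tibble from
#'   [threshold_change_counts()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.threshold_counts <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(direction = sub("^n_", "", .data$direction))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$threshold), .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$subtype)) +
    ggplot2::labs(x = "|z| threshold", y = "gene-sample events") +
    ggplot2::theme_minimal()
}

#' Correlation-sign proportions over cutoffs
#'
#' Proportion of positively vs negatively miRNA-correlated genes among
#' genes passing each |r| cutoff.
#'
#' @param object A `correlation_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.correlation_profile <- function(object, ...) {
  df <- object$by_cutoff |>
    tidyr::pivot_longer(c("prop_positive", "prop_negative"),
                        names_to = "sign", values_to = "proportion") |>
    dplyr::mutate(sign = sub("^prop_", "", .data$sign))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$cutoff), .data$proportion,
                                   fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "|r| cutoff", y = "proportion of genes") +
    ggplot2::theme_minimal()
}

#' Venn partition bar chart
#'
#' Membership-pattern counts from [venn_partition()] as a bar chart (a
#' faithful, plottable rendering of the Venn cells).
#'
#' @param partition Output of [venn_partition()].
#' @return A ggplot.
#' @export
plot_venn_counts <- function(partition) {
  ggplot2::ggplot(partition,
                  ggplot2::aes(stats::reorder(.data$pattern, -.data$n_genes),
                               .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
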