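#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a target call set
#'
#' One row per gene per comparison, with table cells, odds ratio,
#' p-value, q-value and pass flag, plus a `called` flag marking genes in
#' the all-comparison intersection.
#'
#' @param x A `target_call_set` from [call_targets()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method
tidy.target_call_set <- function(x, ...) {
  x$results |>
    dplyr::mutate(assay = x$assay, cell_line = x$cell_line,
                  called = .data$gene_id %in% x$genes) |>
    dplyr::relocate("assay", "cell_line")
}

#' @rdname tidy.target_call_set
#' @return `glance()` returns a one-row summary: assay, cell line,
#'   number of comparisons, family sizes, thresholds and call count.
#' @exportS3Method
glance.target_call_set <- function(x, ...) {
  tibble::tibble(
    assay = x$assay, cell_line = x$cell_line,
    n_comparisons = nrow(x$pairs),
    n_tested_min = min(x$n_tested), n_tested_max = max(x$n_tested),
    or_min = x$thresholds$or_min, q_max = x$thresholds$q_max,
    n_called = length(x$genes)
  )
}

#' Tidy tumor-analysis results
#'
#' @param x A `correlation_profile`, `shared_target_profile` or
#'   `read_counts` object.
#' @param ... Unused.
#' @return A tibble: per-cutoff proportions for a correlation profile,
#'   the shared-count summary for a shared-target profile, per-gene
#'   counts for a `read_counts`.
#' @exportS3Method
tidy.correlation_profile <- function(x, ...) x$by_cutoff

#' @rdname tidy.correlation_profile
#' @exportS3Method
glance.correlation_profile <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$per_gene), n_excluded = x$n_excluded,
    method = x$method,
    mean_r = mean(x$per_gene$r, na.rm = TRUE),
    prop_negative_top = x$by_cutoff$prop_negative[nrow(x$by_cutoff)]
  )
}

#' @rdname tidy.correlation_profile
#' @exportS3Method
tidy.shared_target_profile <- function(x, ...) x$summary

#' @rdname tidy.correlation_profile
#' @exportS3Method
glance.shared_target_profile <- function(x, ...) {
  k <- nrow(x$pairwise)
  tibble::tibble(
    n_targets = nrow(x$per_gene), n_other_mirnas = k,
    fraction_shared_all = x$summary$fraction[x$summary$n_shared == k],
    max_pairwise_p = max(x$pairwise$p_value)
  )
}

#' @rdname tidy.correlation_profile
#' @exportS3Method
tidy.read_counts <- function(x, ...) x$counts

#' @rdname tidy.correlation_profile
#' @exportS3Method
glance.read_counts <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$counts), n_assigned = x$n_assigned,
    n_unassigned = x$n_unassigned, n_ambiguous = x$n_ambiguous,
    n_skipped = x$n_skipped
  )
}
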