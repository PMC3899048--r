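#' Enumerate control-vs-mimic sample pairs
#'
#' All pairwise comparisons of a control and a mimic library within one
#' assay and cell line: the full cross product (2 controls x 2 mimics
#' gives the four comparisons of the canonical design; extra replicates
#' extend it), in deterministic order.
#'
#' @param samples Sample sheet tibble (columns `sample_id`, `assay`,
#'   `condition`, `cell_line`, `replicate`).
#' @param assay `"RIP"` or `"totalRNA"`.
#' @param cell_line Cell-line name.
#' @return Tibble with columns `comparison_id`, `control`, `mimic`.
#' @export
enumerate_pairs <- function(samples, assay, cell_line) {
  sub <- samples[samples$assay == assay & samples$cell_line == cell_line, ]
  controls <- sort(sub$sample_id[sub$condition == "control"])
  mimics <- sort(sub$sample_id[sub$condition == "mimic"])
  if (!length(controls) || !length(mimics)) {
    stop("no ", if (!length(controls)) "control" else "mimic",
         " samples for assay ", assay, " in cell line ", cell_line,
         call. = FALSE)
  }
  tidyr::expand_grid(control = controls, mimic = mimics) |>
    dplyr::mutate(comparison_id = paste(.data$control, .data$mimic,
                                        sep = "_vs_"),
                  .before = 1)
}

#' Build the 2x2 contingency table for one gene in one comparison
#'
#' `a` = reads on the gene in the control library, `b` = reads on all
#' other genes in the control, `c` = reads on the gene in the mimic
#' library, `d` = reads on all other genes in the mimic. Row margins
#' equal the two libraries' assigned-read totals.
#'
#' @param counts An [rip_counts()] object.
#' @param gene_id Gene identifier.
#' @param control,mimic Sample ids of the pair.
#' @return One-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(counts, gene_id, control, mimic) {
  stopifnot(inherits(counts, "rip_counts"))
  if (!gene_id %in% rownames(counts$counts)) {
    stop("gene not in count matrix: ", gene_id, call. = FALSE)
  }
  a <- counts$counts[gene_id, control]
  c_ <- counts$counts[gene_id, mimic]
  tibble::tibble(
    a = as.integer(a),
    b = as.integer(counts$totals[[control]] - a),
    c = as.integer(c_),
    d = as.integer(counts$totals[[mimic]] - c_)
  )
}

#' Test one control-vs-mimic comparison genome-wide
#'
#' For every gene with at least one read across the pair (`a + c > 0`),
#' computes the two-sided Fisher exact p-value of its contingency table,
#' the down-regulation odds ratio, and the BH q-value over all genes
#' tested in this comparison (the multiple-testing family is the
#' comparison). A gene is retained when `odds_ratio > or_min` and
#' `q_value < q_max` (strict inequalities).
#'
#' @param counts An [rip_counts()] object.
#' @param control,mimic Sample ids of the pair.
#' @param or_min Odds-ratio threshold (default 2: at least two-fold
#'   relative depletion under mimic).
#' @param q_max Corrected-p threshold (default 0.001).
#' @return Tibble with one row per tested gene: `gene_id`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p_value`, `q_value`, `pass`; the number of
#'   tested genes (the family size) is in attribute `n_tested`.
#' @export
test_comparison <- function(counts, control, mimic, or_min = 2,
                            q_max = 0.001) {
  stopifnot(inherits(counts, "rip_counts"), or_min > 0, q_max > 0)
  a <- counts$counts[, control]
  c_ <- counts$counts[, mimic]
  testable <- (a + c_) > 0
  a <- a[testable]; c_ <- c_[testable]
  b <- counts$totals[[control]] - a
  d <- counts$totals[[mimic]] - c_
  p <- fisher_exact_two_sided(a, b, c_, d)
  or <- odds_ratio_down(a, b, c_, d)
  q <- bh_adjust(p)
  out <- tibble::tibble(
    gene_id = rownames(counts$counts)[testable],
    a = as.integer(a), b = as.integer(b),
    c = as.integer(c_), d = as.integer(d),
    odds_ratio = or, p_value = p, q_value = q,
    pass = !is.na(or) & or > or_min & q < q_max
  )
  attr(out, "n_tested") <- nrow(out)
  out
}

#' Call high-confidence targets for one assay and cell line
#'
#' Runs [test_comparison()] for every control-vs-mimic pair of the assay
#' and cell line and retains only genes that pass the odds-ratio and
#' q-value thresholds in **every** comparison — the strict intersection
#' that defines the high-confidence target set.
#'
#' @param counts An [rip_counts()] object.
#' @param assay `"RIP"` or `"totalRNA"`.
#' @param cell_line Cell-line name.
#' @inheritParams test_comparison
#' @return An object of class `"target_call_set"`: list with `assay`,
#'   `cell_line`, `genes` (character vector of called genes), `results`
#'   (per-gene per-comparison tibble), `pairs`, `thresholds`,
#'   `n_tested` (named per-comparison family sizes).
#' @export
call_targets <- function(counts, assay, cell_line, or_min = 2,
                         q_max = 0.001) {
  pairs <- enumerate_pairs(counts$samples, assay, cell_line)
  res <- purrr::pmap(pairs, function(comparison_id, control, mimic) {
    r <- test_comparison(counts, control, mimic, or_min, q_max)
    r$comparison_id <- comparison_id
    r
  })
  n_tested <- stats::setNames(
    vapply(res, function(r) attr(r, "n_tested"), integer(1)),
    pairs$comparison_id
  )
  results <- dplyr::bind_rows(res) |>
    dplyr::relocate("comparison_id")
  called <- intersect_comparisons(results)
  structure(
    list(
      assay = assay, cell_line = cell_line, genes = called,
      results = results, pairs = pairs,
      thresholds = list(or_min = or_min, q_max = q_max),
      n_tested = n_tested
    ),
    class = "target_call_set"
  )
}

#' Intersect per-comparison call sets
#'
#' Genes that pass in every comparison present in a per-comparison
#' results tibble (column `pass` by `comparison_id`).
#'
#' @param results Tibble with columns `comparison_id`, `gene_id`, `pass`
#'   (as produced inside [call_targets()]).
#' @return Sorted character vector of genes passing all comparisons.
#' @export
intersect_comparisons <- function(results) {
  stopifnot(all(c("comparison_id", "gene_id", "pass") %in% names(results)))
  n_comp <- length(unique(results$comparison_id))
  if (n_comp == 0) return(character())
  results |>
    dplyr::filter(.data$pass) |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n == n_comp) |>
    dplyr::pull("gene_id") |>
    sort()
}

#' @export
print.target_call_set <- function(x, ...) {
  cat("<target_call_set> ", x$assay, " / ", x$cell_line, ": ",
      length(x$genes), " genes called across ", nrow(x$pairs),
      " comparisons (OR > ", x$thresholds$or_min, ", q < ",
      x$thresholds$q_max, ")\n", sep = "")
  invisible(x)
}

#' Combine RIP-seq and RNA-seq call sets of one cell line
#'
#' @param rip,rna `target_call_set` objects for the two assays of the
#'   same cell line.
#' @return Tibble with one row per gene in the union: `gene_id`,
#'   `in_rip`, `in_rna`, `both`; genes negatively impacted by either
#'   method form the union, `both` marks the cross-method intersection.
#' @export
combine_assays <- function(rip, rna) {
  stopifnot(inherits(rip, "target_call_set"),
            inherits(rna, "target_call_set"))
  if (rip$cell_line != rna$cell_line) {
    stop("cell-line mismatch: ", rip$cell_line, " vs ", rna$cell_line,
         call. = FALSE)
  }
  genes <- sort(union(rip$genes, rna$genes))
  tibble::tibble(
    gene_id = genes,
    in_rip = genes %in% rip$genes,
    in_rna = genes %in% rna$genes,
    both = genes %in% rip$genes & genes %in% rna$genes
  )
}

#' Combine per-cell-line union sets
#'
#' @param sets Named list of character vectors (one union gene set per
#'   cell line).
#' @return Tibble with one row per gene in the combined union: `gene_id`,
#'   one logical column per cell line, and `shared` (`TRUE` when present
#'   in every cell line).
#' @export
combine_cell_lines <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  genes <- sort(unique(unlist(sets)))
  flags <- purrr::map_dfc(sets, function(s) genes %in% s)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = genes), flags)
  out$shared <- Reduce(`&`, flags)
  out
}

#' Annotate a called gene set with prediction-catalog membership
#'
#' Flags each called gene with its membership in every tool's predicted
#' target list for the given miRNA, and keeps the subset predicted by at
#' least one tool.
#'
#' @param genes Character vector of called genes.
#' @param catalog Prediction catalog tibble (`tool`, `mirna`, `gene_id`),
#'   e.g. from [simulate_predictions()] or [read_prediction_catalog()].
#' @param mirna miRNA name to look up.
#' @return Tibble with one row per called gene: `gene_id`, one logical
#'   column per tool, and `predicted` (any tool). Attribute `n_predicted`
#'   holds the predicted-subset size.
#' @export
annotate_with_predictions <- function(genes, catalog, mirna) {
  cat_sub <- catalog[catalog$mirna == mirna, ]
  if (!nrow(cat_sub)) {
    stop("miRNA absent from catalog: ", mirna, call. = FALSE)
  }
  tools <- sort(unique(cat_sub$tool))
  out <- tibble::tibble(gene_id = sort(unique(genes)))
  for (tl in tools) {
    out[[tl]] <- out$gene_id %in% cat_sub$gene_id[cat_sub$tool == tl]
  }
  out$predicted <- Reduce(`|`, out[tools])
  attr(out, "n_predicted") <- sum(out$predicted)
  out
}

#' Cross-method fold-change difference for method-exclusive genes
#'
#' For each gene called by exactly one of the two assays, compares its
#' average log2 fold change (control over mimic, on read-rate scale with
#' a +0.5 pseudocount on gene counts) between the assay where it was
#' identified and the other assay. A large positive difference means the
#' gene's depletion is specific to the identifying assay rather than a
#' near-threshold fluctuation.
#'
#' @param counts An [rip_counts()] object covering both assays.
#' @param rip,rna `target_call_set` objects for the two assays of one
#'   cell line.
#' @return Tibble with one row per method-exclusive gene: `gene_id`,
#'   `called_in`, `lfc_rip`, `lfc_rna`, `lfc_identified`, `lfc_other`,
#'   `difference` (log2 units). Attribute `fraction_above_1` gives the
#'   fraction of genes with `difference > 1` (`NA` when no
#'   method-exclusive genes exist).
#' @export
cross_method_fc_difference <- function(counts, rip, rna) {
  comb <- combine_assays(rip, rna)
  excl <- comb[xor(comb$in_rip, comb$in_rna), ]
  lfc <- function(assay, genes) {
    pairs <- enumerate_pairs(counts$samples, assay, rip$cell_line)
    per_pair <- purrr::pmap(pairs, function(comparison_id, control, mimic) {
      a <- counts$counts[genes, control] + 0.5
      c_ <- counts$counts[genes, mimic] + 0.5
      log2((a / counts$totals[[control]]) / (c_ / counts$totals[[mimic]]))
    })
    Reduce(`+`, per_pair) / length(per_pair)
  }
  if (!nrow(excl)) {
    out <- tibble::tibble(
      gene_id = character(), called_in = character(),
      lfc_rip = numeric(), lfc_rna = numeric(),
      lfc_identified = numeric(), lfc_other = numeric(),
      difference = numeric()
    )
    attr(out, "fraction_above_1") <- NA_real_
    return(out)
  }
  lfc_rip <- lfc("RIP", excl$gene_id)
  lfc_rna <- lfc("totalRNA", excl$gene_id)
  out <- tibble::tibble(
    gene_id = excl$gene_id,
    called_in = ifelse(excl$in_rip, "RIP", "totalRNA"),
    lfc_rip = unname(lfc_rip),
    lfc_rna = unname(lfc_rna)
  ) |>
    dplyr::mutate(
      lfc_identified = ifelse(.data$called_in == "RIP", .data$lfc_rip,
                              .data$lfc_rna),
      lfc_other = ifelse(.data$called_in == "RIP", .data$lfc_rna,
                         .data$lfc_rip),
      difference = .data$lfc_identified - .data$lfc_other
    )
  attr(out, "fraction_above_1") <- mean(out$difference > 1)
  out
}
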