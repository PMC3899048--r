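#' Hypergeometric enrichment of an identified set against one tool
#'
#' Tests whether an experimentally identified gene set contains more
#' predicted targets of a miRNA (per one prediction tool) than expected
#' by chance, over an expressed-gene background: `K` = predicted genes in
#' the background, `n` = identified genes, `k` = identified genes that
#' are predicted, `N` = background size, p = upper tail of
#' `Hypergeometric(N, K, n)` at `k`.
#'
#' @param identified Character vector of identified genes; must be a
#'   subset of `background`.
#' @param catalog Prediction catalog tibble (`tool`, `mirna`, `gene_id`).
#' @param tool,mirna Which predictor and miRNA to test against.
#' @param background Character vector: the expressed-gene background
#'   (see [expressed_background()]).
#' @return One-row tibble: `tool`, `mirna`, `k`, `n`, `K`, `N`,
#'   `p_value`.
#' @export
enrichment_vs_tool <- function(identified, catalog, tool, mirna,
                               background) {
  identified <- unique(identified)
  background <- unique(background)
  outside <- setdiff(identified, background)
  if (length(outside)) {
    stop("identified set is not contained in the background (",
         length(outside), " gene(s) outside); check background configuration",
         call. = FALSE)
  }
  predicted <- catalog$gene_id[catalog$tool == tool & catalog$mirna == mirna]
  K <- length(intersect(predicted, background))
  n <- length(identified)
  k <- length(intersect(identified, intersect(predicted, background)))
  N <- length(background)
  tibble::tibble(
    tool = tool, mirna = mirna,
    k = k, n = n, K = K, N = N,
    p_value = hypergeom_overlap_test(k, K, n, N)
  )
}

#' Venn partition of 2-4 named gene sets
#'
#' Counts genes in every non-empty membership pattern of the given sets
#' (the cells of a Venn diagram). Counts over all patterns sum to the
#' size of the union.
#'
#' @param sets Named list of 2-4 character vectors.
#' @return Tibble with one logical membership column per set, a
#'   `pattern` label (e.g. `"A&B"`), and `n_genes`.
#' @examples
#' venn_partition(list(rip = c("A", "B"), rna = c("B", "C")))
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (length(sets) < 2 || length(sets) > 4) {
    stop("venn_partition takes between 2 and 4 sets", call. = FALSE)
  }
  genes <- sort(unique(unlist(sets)))
  member <- purrr::map_dfc(sets, function(s) genes %in% s)
  patterns <- tidyr::expand_grid(!!!stats::setNames(
    rep(list(c(TRUE, FALSE)), length(sets)), names(sets)
  )) |>
    dplyr::filter(dplyr::if_any(dplyr::everything()))
  patterns$pattern <- apply(patterns, 1, function(row) {
    paste(names(sets)[unlist(row)], collapse = "&")
  })
  patterns$n_genes <- apply(
    patterns[names(sets)], 1,
    function(row) {
      if (!length(genes)) return(0L)
      sum(apply(member, 1, function(m) all(m == unlist(row))))
    }
  )
  patterns |>
    dplyr::relocate("pattern") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(names(sets)), dplyr::desc))
}

#' Shared-target profile of a miRNA against other miRNAs' predictions
#'
#' For each identified target of the focal miRNA, counts how many other
#' miRNAs also predict it (0 to `length(other_sets)`), summarises the
#' distribution of those shared-target classes, and tests each pairwise
#' overlap against the expressed background with the hypergeometric
#' upper-tail test. The top class ("shared by all") corresponds to genes
#' potentially co-regulated by the focal miRNA and every other miRNA
#' considered.
#'
#' @param targets Character vector: identified targets of the focal
#'   miRNA.
#' @param other_sets Named list of character vectors: predicted target
#'   sets of the other miRNAs (typically the per-miRNA union over
#'   prediction tools, see [catalog_gene_sets()]).
#' @param background Character vector for the pairwise overlap tests
#'   (e.g. the expressed background).
#' @return A list of class `"shared_target_profile"`: `per_gene` (tibble
#'   `gene_id`, `n_shared`, one logical column per other miRNA),
#'   `summary` (tibble `n_shared`, `n_genes`, `fraction`, fractions
#'   summing to 1), `pairwise` (tibble `mirna`, `k`, `n`, `K`, `N`,
#'   `p_value`).
#' @export
shared_target_profile <- function(targets, other_sets, background) {
  stopifnot(is.list(other_sets), length(other_sets) >= 1,
            !is.null(names(other_sets)))
  targets <- sort(unique(targets))
  per_gene <- tibble::tibble(gene_id = targets)
  for (nm in names(other_sets)) {
    per_gene[[nm]] <- per_gene$gene_id %in% other_sets[[nm]]
  }
  per_gene$n_shared <- rowSums(per_gene[names(other_sets)])
  summary <- tibble::tibble(n_shared = 0:length(other_sets)) |>
    dplyr::left_join(
      dplyr::count(per_gene, .data$n_shared, name = "n_genes"),
      by = "n_shared"
    ) |>
    dplyr::mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      fraction = if (nrow(per_gene)) .data$n_genes / nrow(per_gene) else 0
    )
  background <- unique(background)
  t_bg <- intersect(targets, background)
  pairwise <- purrr::imap_dfr(other_sets, function(s, nm) {
    s_bg <- intersect(unique(s), background)
    tibble::tibble(
      mirna = nm,
      k = length(intersect(t_bg, s_bg)),
      n = length(t_bg), K = length(s_bg), N = length(background),
      p_value = hypergeom_overlap_test(
        length(intersect(t_bg, s_bg)), length(s_bg), length(t_bg),
        length(background)
      )
    )
  })
  structure(
    list(per_gene = per_gene, summary = summary, pairwise = pairwise),
    class = "shared_target_profile"
  )
}

#' @export
print.shared_target_profile <- function(x, ...) {
  cat("<shared_target_profile> ", nrow(x$per_gene), " focal targets vs ",
      nrow(x$pairwise), " other miRNA(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Per-miRNA gene sets from a prediction catalog
#'
#' Collapses a catalog to one gene set per miRNA (union over tools),
#' the representation used for multi-miRNA shared-target analysis.
#'
#' @param catalog Prediction catalog tibble (`tool`, `mirna`, `gene_id`).
#' @param mirnas miRNAs to extract (default: all in the catalog).
#' @return Named list of character vectors.
#' @export
catalog_gene_sets <- function(catalog, mirnas = unique(catalog$mirna)) {
  stats::setNames(
    lapply(mirnas, function(m) {
      sort(unique(catalog$gene_id[catalog$mirna == m]))
    }),
    mirnas
  )
}

#' Read and write prediction catalogs as gene-list files
#'
#' A catalog on disk is a set of plain-text gene lists, one gene symbol
#' per line, `#`-comments and blank lines ignored, one file per
#' (tool, miRNA) pair. `read_prediction_catalog()` takes a tibble or
#' data frame manifest with columns `tool`, `mirna`, `path`;
#' `write_prediction_catalog()` writes files named
#' `<tool>_<mirna>.txt` under `dir` and returns that manifest.
#'
#' @param manifest Data frame with columns `tool`, `mirna`, `path`.
#' @param catalog Prediction catalog tibble.
#' @param dir Output directory (created if needed).
#' @return `read_prediction_catalog()` returns a catalog tibble
#'   (`tool`, `mirna`, `gene_id`); `write_prediction_catalog()` the
#'   manifest tibble.
#' @export
read_prediction_catalog <- function(manifest) {
  stopifnot(all(c("tool", "mirna", "path") %in% names(manifest)))
  purrr::pmap_dfr(manifest, function(tool, mirna, path) {
    lines <- readr::read_lines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    tibble::tibble(tool = tool, mirna = mirna, gene_id = unique(lines))
  })
}

#' @rdname read_prediction_catalog
#' @export
write_prediction_catalog <- function(catalog, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  keys <- dplyr::distinct(catalog, .data$tool, .data$mirna)
  paths <- purrr::pmap_chr(keys, function(tool, mirna) {
    safe <- function(x) gsub("[^A-Za-z0-9._-]", "-", x)
    path <- file.path(dir, paste0(safe(tool), "_", safe(mirna), ".txt"))
    genes <- catalog$gene_id[catalog$tool == tool & catalog$mirna == mirna]
    readr::write_lines(sort(unique(genes)), path)
    path
  })
  dplyr::mutate(keys, path = paths)
}
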