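#' Tumor expression z-score container
#'
#' Holds a gene-by-sample matrix of expression z-scores relative to
#' normal tissue together with per-sample subtype labels.
#'
#' @param z Numeric matrix, rows = genes (rownames = gene ids), columns =
#'   samples (colnames = sample ids). `NA` marks missing measurements.
#' @param samples Data frame with columns `sample_id` and `subtype`
#'   (one row per column of `z`; samples without a subtype should carry
#'   an explicit label such as `"unlabeled"`).
#' @return An object of class `"zscore_experiment"`.
#' @export
zscore_experiment <- function(z, samples) {
  stopifnot(is.matrix(z), is.data.frame(samples))
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "subtype") %in% names(samples))) {
    stop("sample sheet needs columns sample_id and subtype", call. = FALSE)
  }
  if (!setequal(colnames(z), samples$sample_id) ||
      ncol(z) != nrow(samples)) {
    stop("z-score columns and sample sheet rows must match one-to-one",
         call. = FALSE)
  }
  if (any(is.infinite(z))) {
    stop("z-scores must be finite or NA", call. = FALSE)
  }
  z <- z[, samples$sample_id, drop = FALSE]
  structure(list(z = z, samples = samples), class = "zscore_experiment")
}

#' @export
print.zscore_experiment <- function(x, ...) {
  cat("<zscore_experiment> ", nrow(x$z), " genes x ", ncol(x$z),
      " samples\n", sep = "")
  print(dplyr::count(x$samples, .data$subtype))
  invisible(x)
}

#' Classify a z-score as up-, down-regulated or excluded
#'
#' Up if `z > 0`, down if `z < 0`; a z-score of exactly 0 or a missing
#' value carries no direction and is excluded.
#'
#' @param z Numeric vector of z-scores (NA allowed).
#' @return Factor with levels `up`, `down`, `excluded`.
#' @examples
#' classify_direction(c(0.3, -0.0001, 0, NA))
#' @export
classify_direction <- function(z) {
  out <- ifelse(is.na(z) | z == 0, "excluded", ifelse(z > 0, "up", "down"))
  factor(out, levels = c("up", "down", "excluded"))
}

#' Directional-bias test for one feature across tumor samples
#'
#' Classifies each sample's z-score as up or down and tests whether the
#' down-proportion departs from 0.5 with the exact two-tailed binomial
#' test ([binomial_direction_test()]), as used to ask whether a miRNA
#' shows a consistent direction of dysregulation across a tumor cohort.
#'
#' @param values Numeric vector of z-scores for one feature across
#'   samples (NA allowed).
#' @param null_proportion Null down-proportion (default 0.5).
#' @return An object of class `"directional_bias"`: a one-row tibble with
#'   `n_up`, `n_down`, `n_excluded`, `proportion_down`, `p_value`,
#'   `ci_low`, `ci_high`.
#' @examples
#' directional_bias(c(-2, -1.5, -0.7, -0.1, 0.4, -3))
#' @export
directional_bias <- function(values, null_proportion = 0.5) {
  dir <- classify_direction(values)
  n_up <- sum(dir == "up")
  n_down <- sum(dir == "down")
  n_excluded <- sum(dir == "excluded")
  if (n_up + n_down == 0) {
    stop("all values excluded (zero or missing): no direction to test",
         call. = FALSE)
  }
  bt <- binomial_direction_test(n_down, n_up + n_down, null_proportion)
  out <- tibble::tibble(
    n_up = n_up, n_down = n_down, n_excluded = n_excluded,
    proportion_down = bt$proportion_down,
    p_value = bt$p_value, ci_low = bt$ci_low, ci_high = bt$ci_high
  )
  class(out) <- c("directional_bias", class(out))
  out
}

#' Thresholded up/down change counts, optionally by subtype
#'
#' For each threshold `t`, counts gene-sample events with `z > t` (up)
#' and `z < -t` (down). A gene changed in several samples contributes one
#' event per sample in which it passes the threshold. With
#' `stratify_by_subtype = TRUE` events are tallied within each subtype.
#'
#' @param zscores A [zscore_experiment()].
#' @param thresholds Positive absolute z-score thresholds (default
#'   `c(2, 3, 4, 5)`).
#' @param stratify_by_subtype Tally per subtype (default `TRUE`).
#' @return Tibble with columns `threshold`, (`subtype`,) `n_up`,
#'   `n_down`, and the corresponding proportions among counted events.
#' @export
threshold_change_counts <- function(zscores, thresholds = c(2, 3, 4, 5),
                                    stratify_by_subtype = TRUE) {
  stopifnot(inherits(zscores, "zscore_experiment"), all(thresholds > 0))
  long <- tibble::tibble(
    sample_id = rep(colnames(zscores$z), each = nrow(zscores$z)),
    z = as.vector(zscores$z)
  ) |>
    dplyr::left_join(zscores$samples, by = "sample_id")
  if (!stratify_by_subtype) long$subtype <- "all"
  out <- purrr::map_dfr(thresholds, function(t) {
    long |>
      dplyr::group_by(.data$subtype) |>
      dplyr::summarise(
        threshold = t,
        n_up = sum(.data$z > t, na.rm = TRUE),
        n_down = sum(.data$z < -t, na.rm = TRUE),
        .groups = "drop"
      )
  }) |>
    dplyr::mutate(
      prop_up = ifelse(.data$n_up + .data$n_down > 0,
                       .data$n_up / (.data$n_up + .data$n_down), NA_real_),
      prop_down = ifelse(.data$n_up + .data$n_down > 0,
                         .data$n_down / (.data$n_up + .data$n_down), NA_real_)
    ) |>
    dplyr::select("threshold", "subtype", "n_up", "n_down",
                  "prop_up", "prop_down") |>
    dplyr::arrange(.data$threshold, .data$subtype)
  class(out) <- c("threshold_counts", class(out))
  out
}

#' miRNA-target correlation profile over cutoff grid
#'
#' Computes, for each gene, the correlation of its z-scores with a
#' per-sample miRNA z-score vector across samples, then for each cutoff
#' `c` summarises how many genes with `|r| >= c` correlate positively vs
#' negatively. A predominance of negative correlations at high cutoffs is
#' the expected signature of genuine miRNA targeting.
#'
#' @param mir_values Named numeric vector of miRNA z-scores (names =
#'   sample ids, aligned with the matrix columns).
#' @param zscores A [zscore_experiment()].
#' @param cutoffs Correlation-magnitude cutoffs in `[0, 1)` (default
#'   `seq(0, 0.5, by = 0.1)`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `"correlation_profile"`: list with
#'   `per_gene` (tibble `gene_id`, `r`, `n_pairs`), `by_cutoff` (tibble
#'   `cutoff`, `n_positive`, `n_negative`, `prop_positive`,
#'   `prop_negative`) and `n_excluded` (genes with undefined `r`:
#'   zero variance or fewer than 3 complete pairs).
#' @export
correlation_profile <- function(mir_values, zscores,
                                cutoffs = seq(0, 0.5, by = 0.1),
                                method = c("pearson", "spearman")) {
  stopifnot(inherits(zscores, "zscore_experiment"))
  method <- match.arg(method)
  if (any(cutoffs < 0 | cutoffs >= 1)) {
    stop("cutoffs must lie in [0, 1)", call. = FALSE)
  }
  ids <- colnames(zscores$z)
  if (is.null(names(mir_values))) {
    if (length(mir_values) != length(ids)) {
      stop("unnamed mir_values must match the number of samples", call. = FALSE)
    }
    names(mir_values) <- ids
  }
  if (!all(ids %in% names(mir_values))) {
    stop("mir_values lacks entries for some samples", call. = FALSE)
  }
  if (ncol(zscores$z) < 3) stop("need at least 3 samples", call. = FALSE)
  mir <- mir_values[ids]

  rs <- apply(zscores$z, 1, function(g) {
    ok <- !is.na(g) & !is.na(mir)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(g[ok]) == 0 || stats::sd(mir[ok]) == 0) return(NA_real_)
    stats::cor(g[ok], mir[ok], method = method)
  })
  n_pairs <- apply(zscores$z, 1, function(g) sum(!is.na(g) & !is.na(mir)))
  per_gene <- tibble::tibble(gene_id = rownames(zscores$z), r = unname(rs),
                             n_pairs = as.integer(unname(n_pairs)))
  n_excluded <- sum(is.na(rs))
  if (n_excluded > 0) {
    message(n_excluded, " gene(s) with undefined correlation excluded")
  }
  valid <- rs[!is.na(rs)]
  by_cutoff <- purrr::map_dfr(cutoffs, function(cc) {
    passing <- valid[abs(valid) >= cc]
    n_pos <- sum(passing > 0)
    n_neg <- sum(passing < 0)
    tibble::tibble(
      cutoff = cc, n_positive = n_pos, n_negative = n_neg,
      prop_positive = ifelse(n_pos + n_neg > 0, n_pos / (n_pos + n_neg),
                             NA_real_),
      prop_negative = ifelse(n_pos + n_neg > 0, n_neg / (n_pos + n_neg),
                             NA_real_)
    )
  })
  structure(
    list(per_gene = per_gene, by_cutoff = by_cutoff,
         n_excluded = as.integer(n_excluded), method = method),
    class = "correlation_profile"
  )
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("<correlation_profile> ", nrow(x$per_gene) - x$n_excluded,
      " genes (", x$n_excluded, " excluded), ", x$method,
      " correlation\n", sep = "")
  print(x$by_cutoff)
  invisible(x)
}

#' Read and write z-score matrices as TSV
#'
#' The z-matrix TSV has `gene_id` as its first column and one column per
#' sample; the companion sample sheet maps `sample_id` to `subtype`.
#'
#' @param zscores A [zscore_experiment()].
#' @param z_path,samples_path TSV file paths.
#' @return `read_zscore_matrix()` returns a [zscore_experiment()];
#'   `write_zscore_matrix()` returns its input invisibly.
#' @export
write_zscore_matrix <- function(zscores, z_path, samples_path) {
  stopifnot(inherits(zscores, "zscore_experiment"))
  tbl <- tibble::as_tibble(zscores$z, rownames = "gene_id")
  readr::write_tsv(tbl, z_path)
  readr::write_tsv(zscores$samples, samples_path)
  invisible(zscores)
}

#' @rdname write_zscore_matrix
#' @export
read_zscore_matrix <- function(z_path, samples_path) {
  tbl <- readr::read_tsv(z_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  zscore_experiment(m, samples)
}
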