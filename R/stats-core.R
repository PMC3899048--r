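#' Two-sided Fisher exact test for 2x2 read-count tables
#'
#' Computes the two-sided Fisher exact p-value for one or more 2x2
#' contingency tables of the form used in RIP-seq / RNA-seq differential
#' association testing: `a` reads on the gene in the control sample, `b`
#' reads on all other genes in the control, `c` reads on the gene in the
#' treatment (miRNA-mimic) sample, `d` reads on all other genes in the
#' treatment.
#'
#' The two-sided p-value follows the probability-sum convention: it is the
#' sum of the probabilities of all tables with the same margins whose
#' hypergeometric probability does not exceed that of the observed table
#' (the same convention as [stats::fisher.test()], including its relative
#' tolerance of `1e-7` when comparing probabilities, so the two agree to
#' floating-point accuracy). All four arguments are vectorised; the
#' computation is performed in blocks over the pooled hypergeometric
#' support, which makes genome-wide sweeps (thousands of tables with
#' library-scale margins) practical.
#'
#' @param a,b,c,d Non-negative integer vectors of equal length (or length
#'   1, recycled): the four cells of each table.
#' @param chunk_size Maximum number of pooled support points evaluated per
#'   block; bounds peak memory for deep libraries.
#' @return Numeric vector of two-sided p-values in `[0, 1]`.
#' @examples
#' fisher_exact_two_sided(10, 90, 10, 90)   # identical proportions -> 1
#' fisher_exact_two_sided(20, 980, 5, 995)
#' @seealso [odds_ratio_down()], [bh_adjust()]
#' @export
fisher_exact_two_sided <- function(a, b, c, d, chunk_size = 2e6) {
  tab <- recycle_cells(a, b, c, d)
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  if (any(a + b + c + d == 0)) {
    stop("empty contingency table: all four cells are zero", call. = FALSE)
  }
  m1 <- a + b          # control margin
  m2 <- c + d          # treatment margin
  k  <- a + c          # gene margin
  lo <- pmax(0L, k - m2)
  hi <- pmin(k, m1)
  len <- hi - lo + 1
  p_obs <- stats::dhyper(a, m1, m2, k)
  out <- numeric(length(a))

  # process tables in blocks whose pooled support fits in chunk_size
  csum <- cumsum(as.numeric(len))
  block <- findInterval(csum - 1, seq(0, csum[length(csum)], by = chunk_size))
  for (blk in split(seq_along(a), block)) {
    idx <- rep.int(blk, len[blk])
    xs <- sequence(len[blk]) - 1 + rep.int(lo[blk], len[blk])
    probs <- stats::dhyper(xs, m1[idx], m2[idx], k[idx])
    keep <- probs <= p_obs[idx] * (1 + 1e-7)
    sums <- rowsum(probs * keep, group = idx, reorder = TRUE)
    out[blk] <- sums[match(blk, sort(blk)), 1L]
  }
  pmin(out, 1)
}

#' Down-regulation-oriented odds ratio for a 2x2 read-count table
#'
#' Cross-product odds ratio oriented so that values above 1 indicate
#' relative depletion of the gene in the treatment sample:
#' `(a/b) / (c/d) = a*d / (b*c)`. A gene whose reads vanish entirely under
#' treatment (`c = 0` with `a > 0`) yields `Inf`, which passes any finite
#' down-regulation threshold. Tables with no reads on the gene in either
#' sample (`a = c = 0`) are untestable and yield `NA`.
#'
#' @inheritParams fisher_exact_two_sided
#' @return Numeric vector of odds ratios (possibly `Inf` or `NA`).
#' @examples
#' odds_ratio_down(20, 980, 5, 995)  # ~4.06: four-fold relative depletion
#' @export
odds_ratio_down <- function(a, b, c, d) {
  tab <- recycle_cells(a, b, c, d)
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  if (any(b == 0 & d == 0)) {
    stop("odds ratio undefined: no reads on other genes in either sample (b = d = 0)",
         call. = FALSE)
  }
  or <- (a * d) / (b * c)
  or[a == 0 & c == 0] <- NA_real_
  or
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-adjusted q-values in the input order, capped at 1. Thin
#' wrapper over [stats::p.adjust()] with `method = "BH"` so that every
#' caller in the pipeline shares one spelling of the correction.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (may be empty).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1] and contain no NA", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing at least `k` predicted genes when `n` genes are
#' sampled without replacement from a background of `N` genes of which `K`
#' are predicted: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This is
#' the enrichment test used to compare an experimentally identified gene
#' set against a target-prediction catalog over an expressed-gene
#' background.
#'
#' @param k Observed overlap size.
#' @param K Number of predicted genes inside the background.
#' @param n Size of the identified set.
#' @param N Background size.
#' @return Upper-tail p-value in `[0, 1]`. All arguments vectorised.
#' @examples
#' hypergeom_overlap_test(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_overlap_test <- function(k, K, n, N) {
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), m); K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m); N <- rep_len(as.numeric(N), m)
  if (any(k < 0 | K > N | n > N | k > pmin(K, n))) {
    stop("invalid hypergeometric configuration: need 0 <= k <= min(K, n) and K, n <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Exact two-tailed binomial test of directional bias
#'
#' Tests whether the proportion of "down" calls among `n_total` up/down
#' calls departs from `null_proportion`, with the exact two-tailed
#' p-value (sum of outcome probabilities not exceeding that of the
#' observed count) and a 95% Clopper-Pearson confidence interval for the
#' down-proportion, via [stats::binom.test()].
#'
#' @param n_down Number of samples classified as down-regulated.
#' @param n_total Total number of classified (up + down) samples.
#' @param null_proportion Null down-proportion (default 0.5).
#' @return A one-row tibble: `n_down`, `n_total`, `proportion_down`,
#'   `p_value`, `ci_low`, `ci_high`.
#' @examples
#' binomial_direction_test(10, 10)  # p = 2 / 2^10
#' @export
binomial_direction_test <- function(n_down, n_total, null_proportion = 0.5) {
  stopifnot(length(n_down) == 1, length(n_total) == 1)
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_down < 0 || n_down > n_total) {
    stop("n_down must lie in [0, n_total]", call. = FALSE)
  }
  bt <- stats::binom.test(n_down, n_total, p = null_proportion)
  tibble::tibble(
    n_down = as.integer(n_down),
    n_total = as.integer(n_total),
    proportion_down = n_down / n_total,
    p_value = bt$p.value,
    ci_low = bt$conf.int[1],
    ci_high = bt$conf.int[2]
  )
}

#' Relative quantification by the 2^-ddCt method
#'
#' Fold change of a target transcript in a case condition relative to a
#' control condition, each normalised to a reference transcript measured
#' in the same condition: `2^-((Ct_tc - Ct_rc) - (Ct_t0 - Ct_r0))`.
#'
#' @param ct_target_case,ct_ref_case Threshold cycles of target and
#'   reference in the case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Threshold cycles in the control
#'   condition.
#' @return Numeric fold change (vectorised).
#' @examples
#' ddct_fold_change(25, 20, 24, 20)  # 0.5
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

# recycle and validate the four cells of one or more 2x2 tables
recycle_cells <- function(a, b, c, d) {
  m <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, m); b <- rep_len(b, m); c <- rep_len(c, m); d <- rep_len(d, m)
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c), d = as.numeric(d))
}
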