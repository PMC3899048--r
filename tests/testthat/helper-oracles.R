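# Independent brute-force oracles used to verify the package's exact
# statistics. All are written from the definitions with choose()/dbinom()
# and never share code with the implementation under test.

# two-sided Fisher p by enumeration over the margin-constrained support,
# probabilities from binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  pr <- exp(lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k))
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# step-up BH from the definition: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# upper-tail hypergeometric P(X >= k) as a direct sum of coefficient ratios
oracle_hyper <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs) / choose(N, n))
}

# exact two-tailed binomial p: sum of outcome probabilities <= observed
oracle_binom <- function(x, n, p = 0.5) {
  pr <- dbinom(0:n, n, p)
  sum(pr[pr <= pr[x + 1] * (1 + 1e-7)])
}

# small helper: a valid sample sheet for hand-built count matrices
toy_samples <- function(cell_line = "U251", assays = c("RIP", "totalRNA"),
                        n_rep = 2) {
  df <- expand.grid(
    replicate = seq_len(n_rep),
    condition = c("control", "mimic"),
    assay = assays,
    cell_line = cell_line,
    stringsAsFactors = FALSE
  )
  df$sample_id <- paste(df$cell_line, df$assay, df$condition, df$replicate,
                        sep = "_")
  tibble::as_tibble(df[, c("sample_id", "assay", "condition", "cell_line",
                           "replicate")])
}
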