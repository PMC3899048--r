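# small deterministic count object with hand-chosen cells
toy_counts <- function() {
  samples <- toy_samples()
  genes <- sprintf("g%02d", 1:6)
  m <- matrix(100L, nrow = 6, ncol = nrow(samples),
              dimnames = list(genes, samples$sample_id))
  mimics <- samples$sample_id[samples$condition == "mimic" &
                                samples$assay == "RIP"]
  m["g01", mimics] <- 10L   # strong planted depletion in RIP
  m["g02", mimics[1]] <- 10L  # depleted in one mimic only
  rip_counts(m, samples)
}

test_that("pair enumeration is the full control x mimic cross product", {
  samples <- toy_samples()
  pairs <- enumerate_pairs(samples, "RIP", "U251")
  expect_equal(nrow(pairs), 4)  # 2 controls x 2 mimics
  samples3 <- toy_samples(n_rep = 3)
  keep <- !(samples3$condition == "mimic" & samples3$replicate == 3)
  expect_equal(nrow(enumerate_pairs(samples3[keep, ], "RIP", "U251")), 6)
  one <- toy_samples(n_rep = 1)
  expect_equal(nrow(enumerate_pairs(one, "totalRNA", "U251")), 1)
  expect_error(enumerate_pairs(samples[samples$condition == "control", ],
                               "RIP", "U251"), "mimic")
})

test_that("contingency tables reproduce counts and conserve margins", {
  counts <- toy_counts()
  tab <- build_contingency(counts, "g01", "U251_RIP_control_1",
                           "U251_RIP_mimic_1")
  expect_equal(tab$a, 100L)
  expect_equal(tab$a + tab$b, unname(counts$totals[["U251_RIP_control_1"]]))
  expect_equal(tab$c, 10L)
  expect_equal(tab$c + tab$d, unname(counts$totals[["U251_RIP_mimic_1"]]))
  expect_error(build_contingency(counts, "nope", "U251_RIP_control_1",
                                 "U251_RIP_mimic_1"), "nope")
})

test_that("one comparison applies Fisher, BH and both thresholds strictly", {
  counts <- toy_counts()
  res <- test_comparison(counts, "U251_RIP_control_1", "U251_RIP_mimic_1")
  expect_equal(attr(res, "n_tested"), 6L)
  expect_equal(res$q_value, bh_adjust(res$p_value))
  expect_true(all(res$q_value >= res$p_value))
  g1 <- res[res$gene_id == "g01", ]
  expect_true(g1$pass)
  expect_equal(
    g1$p_value,
    fisher_exact_two_sided(g1$a, g1$b, g1$c, g1$d)
  )
  # OR barely below threshold is rejected no matter how small q
  expect_false(with(res[res$gene_id == "g03", ], pass))
})

test_that("threshold inequalities are strict on both sides", {
  samples <- toy_samples(assays = "RIP", n_rep = 1)
  genes <- c("gq", "gor", sprintf("f%02d", 1:8))
  m <- matrix(1000L, nrow = 10, ncol = 2,
              dimnames = list(genes, samples$sample_id))
  m["gor", 2] <- 501L  # OR just under 2
  m["gq", 2] <- 200L
  counts <- rip_counts(m, samples)
  res <- test_comparison(counts, samples$sample_id[1], samples$sample_id[2])
  gor <- res[res$gene_id == "gor", ]
  expect_lt(gor$odds_ratio, 2)
  expect_false(gor$pass)
  # same table but with q forced above 0.001 via q_max
  gq <- res[res$gene_id == "gq", ]
  expect_true(gq$q_value < 0.001 && gq$pass)
  res2 <- test_comparison(counts, samples$sample_id[1], samples$sample_id[2],
                          q_max = gq$q_value)  # strict: q < q_max fails at equality
  expect_false(res2[res2$gene_id == "gq", ]$pass)
})

test_that("genes with no reads in a pair are excluded from the family", {
  samples <- toy_samples(assays = "RIP", n_rep = 1)
  m <- matrix(c(50L, 0L, 10L, 60L, 0L, 2L), nrow = 3,
              dimnames = list(c("g1", "g0", "g2"), samples$sample_id))
  counts <- rip_counts(m, samples)
  res <- test_comparison(counts, samples$sample_id[1], samples$sample_id[2])
  expect_false("g0" %in% res$gene_id)
  expect_equal(attr(res, "n_tested"), 2L)
})

test_that("calling intersects across all comparisons", {
  counts <- toy_counts()
  tc <- call_targets(counts, "RIP", "U251")
  # g01 depleted in both mimics -> in all four comparisons
  expect_equal(tc$genes, "g01")
  # g02 depleted in only one mimic -> present in 2/4 comparisons, not called
  per_comp <- tc$results |>
    dplyr::filter(pass) |>
    dplyr::count(gene_id)
  expect_equal(per_comp$n[per_comp$gene_id == "g02"], 2L)
  expect_equal(nrow(tc$pairs), 4)
  expect_named(tc$n_tested, tc$pairs$comparison_id)
  td <- tidy(tc)
  expect_true(all(td$called == (td$gene_id == "g01")))
  expect_equal(glance(tc)$n_called, 1L)
})

test_that("single-comparison designs reduce intersection to identity", {
  samples <- toy_samples(assays = "RIP", n_rep = 1)
  m <- matrix(c(100L, 1000L, 10L, 1090L), nrow = 2,
              dimnames = list(c("gt", "gn"), samples$sample_id))
  counts <- rip_counts(m, samples)
  tc <- call_targets(counts, "RIP", "U251")
  one <- test_comparison(counts, samples$sample_id[1], samples$sample_id[2])
  expect_setequal(tc$genes, one$gene_id[one$pass])
})

test_that("deeper sequencing can only strengthen a fixed relative effect", {
  # doubling all four cells shrinks the Fisher p
  a <- c(20, 5, 50); b <- c(980, 995, 950); c_ <- c(5, 1, 20); d <- c(995, 999, 980)
  p1 <- fisher_exact_two_sided(a, b, c_, d)
  p2 <- fisher_exact_two_sided(2 * a, 2 * b, 2 * c_, 2 * d)
  expect_true(all(p2 <= p1))
  # call sets grow along a depth ladder with fixed planted effects
  called_at_depth <- vapply(c(5e4, 2e5, 8e5), function(depth) {
    cfg <- sim_config(n_genes = 300, n_targets = 30, rna_effect = 2,
                      rip_effect = 2, reads_per_sample = depth,
                      baseline_sigma = 0.5)
    sim <- simulate_counts(cfg, seed = 55)
    length(call_targets(sim$counts, "RIP", "U251")$genes)
  }, numeric(1))
  expect_true(all(diff(called_at_depth) >= 0))
})

test_that("assay and cell-line combination follow set algebra", {
  mk <- function(assay, cl, genes) {
    structure(list(assay = assay, cell_line = cl, genes = genes,
                   results = NULL, pairs = NULL,
                   thresholds = list(or_min = 2, q_max = 0.001)),
              class = "target_call_set")
  }
  rip <- mk("RIP", "U251", c("A", "B", "C"))
  rna <- mk("totalRNA", "U251", c("B", "C", "D"))
  comb <- combine_assays(rip, rna)
  expect_equal(comb$gene_id, c("A", "B", "C", "D"))
  expect_equal(comb$gene_id[comb$both], c("B", "C"))
  expect_error(combine_assays(rip, mk("totalRNA", "U343", "X")), "mismatch")
  disjoint <- combine_assays(mk("RIP", "U251", "A"), mk("totalRNA", "U251", "B"))
  expect_equal(sum(disjoint$both), 0)

  cl <- combine_cell_lines(list(U251 = c("A", "B"), U343 = c("B", "C")))
  expect_equal(cl$gene_id, c("A", "B", "C"))
  expect_equal(cl$gene_id[cl$shared], "B")
  single <- combine_cell_lines(list(U251 = c("A", "B")))
  expect_true(all(single$shared))
})

test_that("prediction annotation flags per-tool membership", {
  catalog <- tibble::tibble(
    tool = c("TargetScan", "miRanda", "PicTar"),
    mirna = "miR-137",
    gene_id = c("A", "B", "B")
  )
  ann <- annotate_with_predictions(c("A", "B", "C"), catalog, "miR-137")
  expect_equal(ann$TargetScan, c(TRUE, FALSE, FALSE))
  expect_equal(ann$miRanda, c(FALSE, TRUE, FALSE))
  expect_equal(ann$predicted, c(TRUE, TRUE, FALSE))
  expect_equal(attr(ann, "n_predicted"), 2L)
  expect_error(annotate_with_predictions("A", catalog, "miR-7"), "absent")
})

test_that("perfect catalogs recover called-and-true genes exactly", {
  cfg <- sim_config(n_genes = 300, n_targets = 30, rna_effect = 2.5,
                    rip_effect = 1.6, reads_per_sample = 3e5,
                    baseline_sigma = 0.5)
  sim <- simulate_counts(cfg, seed = 60)
  catalog <- simulate_predictions(sim$truth, tools = "T1", sensitivity = 1,
                                  false_rate = 0, seed = 61)
  tc <- call_targets(sim$counts, "RIP", "U251")
  ann <- annotate_with_predictions(tc$genes, catalog, "miR-137")
  truth_set <- sim$truth$gene_id[sim$truth$is_target]
  expect_setequal(ann$gene_id[ann$predicted], intersect(tc$genes, truth_set))
})

test_that("cross-method fold-change difference isolates assay-specific effects", {
  # rip_effect 4, rna_effect 1: RIP-exclusive genes should show ~2 log2
  # units more depletion in RIP than in totalRNA
  cfg <- sim_config(n_genes = 300, n_targets = 30, rna_effect = 1,
                    rip_effect = 4, reads_per_sample = 4e5,
                    baseline_sigma = 0.5)
  sim <- simulate_counts(cfg, seed = 70)
  rip <- call_targets(sim$counts, "RIP", "U251")
  rna <- call_targets(sim$counts, "totalRNA", "U251")
  fc <- cross_method_fc_difference(sim$counts, rip, rna)
  rip_only <- fc[fc$called_in == "RIP", ]
  expect_gt(nrow(rip_only), 10)
  expect_equal(median(rip_only$difference), 2, tolerance = 0.15)
  expect_gt(attr(fc, "fraction_above_1"), 0.9)

  # no method-exclusive genes -> empty result, fraction NA
  mk <- function(assay, genes) {
    structure(list(assay = assay, cell_line = "U251", genes = genes),
              class = "target_call_set")
  }
  empty <- cross_method_fc_difference(sim$counts, mk("RIP", "A"),
                                      mk("totalRNA", "A"))
  expect_equal(nrow(empty), 0)
  expect_true(is.na(attr(empty, "fraction_above_1")))
})

test_that("identical rates in both assays give zero difference", {
  samples <- toy_samples()
  m <- matrix(200L, 2, nrow(samples),
              dimnames = list(c("g1", "g2"), samples$sample_id))
  counts <- rip_counts(m, samples)
  mk <- function(assay, genes) {
    structure(list(assay = assay, cell_line = "U251", genes = genes),
              class = "target_call_set")
  }
  fc <- cross_method_fc_difference(counts, mk("RIP", "g1"),
                                   mk("totalRNA", character()))
  expect_equal(fc$difference, 0)
})
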