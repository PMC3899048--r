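make_ann <- function(...) {
  tibble::tibble(...)
}

test_that("isoform collapsing takes the exon union per gene", {
  ann <- make_ann(
    gene_id = "g1", isoform_id = c("t1", "t2"), chrom = "chr1",
    strand = "+", start = c(0, 50), end = c(100, 150)
  )
  st <- collapse_isoforms(ann)
  expect_equal(nrow(st), 1)
  expect_equal(c(st$start, st$end), c(0, 150))
  expect_equal(super_tx_lengths(st)$total_length, 150)

  disjoint <- make_ann(
    gene_id = "g2", isoform_id = "t1", chrom = "chr1", strand = "-",
    start = c(0, 200), end = c(100, 300)
  )
  st2 <- collapse_isoforms(disjoint)
  expect_equal(nrow(st2), 2)
  expect_equal(super_tx_lengths(st2)$total_length, 200)
})

test_that("collapsing is idempotent and bounds the union length", {
  set.seed(13)
  ann <- purrr::map_dfr(1:20, function(g) {
    n_ex <- sample(1:6, 1)
    starts <- sort(sample(0:5000, n_ex)) + (g - 1) * 10000
    tibble::tibble(
      gene_id = sprintf("g%02d", g),
      isoform_id = sprintf("g%02d.t%d", g, sample(1:3, n_ex, replace = TRUE)),
      chrom = "chr1", strand = "+",
      start = starts, end = starts + sample(50:500, n_ex, replace = TRUE)
    )
  })
  st <- collapse_isoforms(ann)
  again <- collapse_isoforms(
    dplyr::mutate(st, isoform_id = "collapsed")
  )
  expect_equal(st$start, again$start)
  expect_equal(st$end, again$end)
  # blocks sorted, non-overlapping, non-adjacent within each gene
  by_gene <- split(st, st$gene_id)
  for (g in by_gene) {
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # union length between longest isoform and sum of isoform lengths
  lens <- super_tx_lengths(st)
  iso <- ann |>
    dplyr::group_by(gene_id, isoform_id) |>
    dplyr::summarise(len = sum(end - start), .groups = "drop_last") |>
    dplyr::summarise(longest = max(len), total = sum(len), .groups = "drop")
  merged <- dplyr::left_join(lens, iso, by = "gene_id")
  expect_true(all(merged$total_length >= merged$longest))
  expect_true(all(merged$total_length <= merged$total))
})

test_that("a gene split across chromosomes is rejected by name", {
  ann <- make_ann(
    gene_id = "gX", isoform_id = c("t1", "t2"), chrom = c("chr1", "chr2"),
    strand = "+", start = c(0, 0), end = c(100, 100)
  )
  expect_error(collapse_isoforms(ann), "gX")
})

test_that("reads are assigned uniquely, ambiguity discards, totals conserve", {
  ann <- make_ann(
    gene_id = rep(c("gA", "gB"), each = 1),
    isoform_id = c("a1", "b1"), chrom = "chr1", strand = "+",
    start = c(0, 150), end = c(150, 300)
  )
  st <- collapse_isoforms(ann)
  reads <- tibble::tibble(
    chrom = "chr1",
    start = c(10, 140, 200, 400, 5),
    end = c(46, 176, 236, 436, 41),
    strand = "+"
  )
  rc <- count_reads(reads, st)
  # read 2 straddles gA/gB -> ambiguous; read 4 hits nothing
  expect_equal(rc$counts$count[rc$counts$gene_id == "gA"], 2L)
  expect_equal(rc$counts$count[rc$counts$gene_id == "gB"], 1L)
  expect_equal(rc$n_ambiguous, 1L)
  expect_equal(rc$n_unassigned, 1L)
  expect_equal(rc$n_assigned + rc$n_unassigned + rc$n_ambiguous + rc$n_skipped,
               nrow(reads))
})

test_that("malformed intervals are skipped with a warning and counted", {
  ann <- make_ann(gene_id = "g", isoform_id = "t", chrom = "c",
                  strand = "+", start = 0, end = 100)
  st <- collapse_isoforms(ann)
  reads <- tibble::tibble(chrom = "c", start = c(10, 50), end = c(46, 40))
  expect_warning(rc <- count_reads(reads, st), "malformed")
  expect_equal(rc$n_skipped, 1L)
  expect_equal(rc$n_assigned, 1L)
})

test_that("simulated annotation and reads reproduce the planted counts", {
  sim <- simulate_annotation_and_reads(n_genes = 8, n_isoforms = 3,
                                       reads_per_gene = 50, seed = 101)
  st <- collapse_isoforms(sim$annotation)
  rc <- count_reads(sim$alignments, st)
  expect_equal(
    dplyr::arrange(rc$counts, gene_id)$count,
    dplyr::arrange(sim$expected, gene_id)$count
  )
  expect_equal(rc$n_ambiguous + rc$n_unassigned, 0L)
  expect_equal(glance(rc)$n_assigned, sum(sim$expected$count))
})

test_that("expressed background keeps genes with min_count in the cell line", {
  samples <- toy_samples()
  m <- matrix(0L, nrow = 3, ncol = nrow(samples),
              dimnames = list(c("g1", "g2", "g3"), samples$sample_id))
  m["g1", ] <- 5L
  m["g2", samples$sample_id[1]] <- 1L  # single read in one RIP control
  counts <- rip_counts(m, samples)
  bg <- expressed_background(counts, "U251", min_count = 1)
  expect_setequal(bg, c("g1", "g2"))
  expect_setequal(expressed_background(counts, "U251", min_count = 2), "g1")
  expect_error(expressed_background(counts, "HeLa"), "unknown cell line")
})

test_that("GTF and BED round-trip through the readers", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\ttest\texon\t1\t100\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "g1.t1";'),
    paste0("chr1\ttest\texon\t51\t150\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "g1.t2";'),
    paste0("chr1\ttest\texon\t501\t600\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "g2.t1";')
  ), gtf)
  ann <- read_gtf_annotation(gtf)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$start, c(0, 50, 500))  # converted to 0-based half-open
  expect_equal(ann$end, c(100, 150, 600))
  st <- collapse_isoforms(ann)
  expect_equal(super_tx_lengths(st)$total_length, c(150, 100))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t46\tr1\t0\t+", "chr1\t510\t546\tr2\t0\t-"), bed)
  reads <- read_bed_alignments(bed)
  expect_equal(reads$start, c(10, 510))
  rc <- count_reads(reads, st)
  expect_equal(sum(rc$counts$count), 2L)
})

test_that("count matrices round-trip through TSV", {
  sim <- simulate_counts(sim_config(n_genes = 40, n_targets = 5,
                                    reads_per_sample = 2000), seed = 4)
  cp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_count_matrix(sim$counts, cp, sp)
  back <- read_count_matrix(cp, sp)
  expect_equal(back$counts, sim$counts$counts)
  expect_equal(back$samples, sim$counts$samples)
})

test_that("rip_counts validates its inputs", {
  samples <- toy_samples()
  m <- matrix(1L, 2, nrow(samples),
              dimnames = list(c("g1", "g2"), samples$sample_id))
  expect_s3_class(rip_counts(m, samples)$samples, "tbl_df")
  bad <- samples; bad$replicate <- 1L
  expect_error(rip_counts(m, bad), "unique")
  m2 <- m; m2[1, 1] <- -1L
  expect_error(rip_counts(m2, samples), "non-negative")
})
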