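#' Collapse isoforms into per-gene super-transcripts
#'
#' Builds one counting unit per gene by taking the interval union of all
#' exons of all isoforms of that gene (its "super-transcript"). Input and
#' output coordinates are 0-based half-open.
#'
#' @param annotation A data frame with columns `gene_id`, `isoform_id`,
#'   `chrom`, `strand`, `start`, `end` (one row per exon), e.g. from
#'   [read_gtf_annotation()] or [simulate_annotation_and_reads()].
#' @return A tibble with class `"super_tx"`: one row per merged block,
#'   columns `gene_id`, `chrom`, `strand`, `start`, `end`, sorted by
#'   `(chrom, first block start, gene_id)` and by `start` within a gene.
#'   Blocks of a gene never overlap or touch. Use [super_tx_lengths()]
#'   for per-gene union lengths.
#' @examples
#' ann <- tibble::tibble(
#'   gene_id = "g1", isoform_id = c("t1", "t2"), chrom = "chr1",
#'   strand = "+", start = c(0, 50), end = c(100, 150)
#' )
#' collapse_isoforms(ann)  # single block [0, 150)
#' @export
collapse_isoforms <- function(annotation) {
  stopifnot(is.data.frame(annotation), nrow(annotation) > 0)
  req <- c("gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(req, names(annotation))
  if (length(missing_cols)) {
    stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(annotation$start >= annotation$end)) {
    stop("every exon must satisfy start < end (0-based half-open)", call. = FALSE)
  }
  multi <- annotation |>
    dplyr::distinct(.data$gene_id, .data$chrom) |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    stop("gene(s) with exons on multiple chromosomes: ",
         paste(multi$gene_id, collapse = ", "), call. = FALSE)
  }

  blocks <- annotation |>
    dplyr::group_by(.data$gene_id, .data$chrom) |>
    dplyr::reframe(
      strand = .data$strand[1],
      as_block_tbl(IRanges::reduce(
        IRanges::IRanges(start = .data$start + 1, end = .data$end)
      ))
    )
  ord <- blocks |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(.first = min(.data$start)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$.first, .data$gene_id, .data$start) |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end")
  class(ord) <- c("super_tx", class(ord))
  ord
}

# IRanges (1-based closed) -> 0-based half-open block tibble
as_block_tbl <- function(ir) {
  tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Per-gene super-transcript lengths
#'
#' @param super_tx Output of [collapse_isoforms()].
#' @return Tibble `gene_id`, `total_length` (bases in the exon union).
#' @export
super_tx_lengths <- function(super_tx) {
  super_tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(total_length = sum(.data$end - .data$start), .groups = "drop")
}

#' Assign aligned reads to genes and count them
#'
#' A read increments a gene when it overlaps that gene's super-transcript
#' blocks by at least `min_overlap` bases and overlaps no other gene.
#' Reads overlapping no gene are tallied as unassigned, reads overlapping
#' two or more genes as ambiguous; neither contributes to any count.
#' Counting ignores strand unless `same_strand = TRUE` (the originating
#' library protocol is unstranded).
#'
#' @param alignments Data frame of read intervals: columns `chrom`,
#'   `start`, `end` (0-based half-open), optional `strand`.
#' @param super_tx Reference from [collapse_isoforms()].
#' @param min_overlap Minimum overlapping bases for assignment (default 1).
#' @param same_strand If `TRUE`, only same-strand overlaps count.
#' @return A list of class `"read_counts"`: `counts` (tibble `gene_id`,
#'   `count`, one row per reference gene), `n_assigned`, `n_unassigned`,
#'   `n_ambiguous`, `n_skipped` (malformed intervals, dropped with a
#'   warning). `n_assigned + n_unassigned + n_ambiguous + n_skipped`
#'   equals the number of input alignments.
#' @export
count_reads <- function(alignments, super_tx, min_overlap = 1L,
                        same_strand = FALSE) {
  stopifnot(is.data.frame(alignments), inherits(super_tx, "super_tx"))
  gene_ids <- unique(super_tx$gene_id)

  bad <- !is.finite(alignments$start) | !is.finite(alignments$end) |
    alignments$start >= alignments$end
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    warning(n_skipped, " malformed alignment interval(s) skipped", call. = FALSE)
    alignments <- alignments[!bad, , drop = FALSE]
  }

  if (nrow(alignments) == 0) {
    counts <- tibble::tibble(gene_id = gene_ids, count = 0L)
    return(new_read_counts(counts, 0L, 0L, n_skipped))
  }

  ref <- GenomicRanges::GRanges(
    seqnames = super_tx$chrom,
    ranges = IRanges::IRanges(start = super_tx$start + 1, end = super_tx$end),
    strand = if (same_strand) super_tx$strand else "*"
  )
  rd_strand <- if (same_strand && !is.null(alignments$strand)) {
    alignments$strand
  } else "*"
  reads <- GenomicRanges::GRanges(
    seqnames = alignments$chrom,
    ranges = IRanges::IRanges(start = alignments$start + 1, end = alignments$end),
    strand = rd_strand
  )
  hits <- GenomicRanges::findOverlaps(
    reads, ref,
    minoverlap = min_overlap,
    ignore.strand = !same_strand
  )
  hit_gene <- super_tx$gene_id[S4Vectors::subjectHits(hits)]
  hit_read <- S4Vectors::queryHits(hits)
  # a read hitting several blocks of one gene is still one gene hit
  per_read <- tibble::tibble(read = hit_read, gene_id = hit_gene) |>
    dplyr::distinct()
  genes_per_read <- per_read |> dplyr::count(.data$read)
  ambiguous_reads <- genes_per_read$read[genes_per_read$n >= 2]
  assigned <- per_read |> dplyr::filter(!.data$read %in% ambiguous_reads)

  counts <- assigned |>
    dplyr::count(.data$gene_id, name = "count") |>
    dplyr::right_join(tibble::tibble(gene_id = gene_ids), by = "gene_id") |>
    dplyr::mutate(count = as.integer(dplyr::coalesce(.data$count, 0L))) |>
    dplyr::arrange(match(.data$gene_id, gene_ids))
  n_ambiguous <- length(ambiguous_reads)
  n_unassigned <- nrow(alignments) - nrow(assigned) - n_ambiguous
  new_read_counts(counts, n_unassigned, n_ambiguous, n_skipped)
}

new_read_counts <- function(counts, n_unassigned, n_ambiguous, n_skipped) {
  structure(
    list(
      counts = counts,
      n_assigned = sum(counts$count),
      n_unassigned = as.integer(n_unassigned),
      n_ambiguous = as.integer(n_ambiguous),
      n_skipped = as.integer(n_skipped)
    ),
    class = "read_counts"
  )
}

#' @export
print.read_counts <- function(x, ...) {
  cat("<read_counts> ", x$n_assigned, " assigned, ", x$n_unassigned,
      " unassigned, ", x$n_ambiguous, " ambiguous, ", x$n_skipped,
      " skipped\n", sep = "")
  invisible(x)
}

#' Construct a count matrix with sample metadata
#'
#' The central container for the differential stage: an integer gene-by-
#' sample read-count matrix plus a sample sheet describing each library.
#'
#' @param counts Integer matrix, rows = genes (rownames = gene ids),
#'   columns = samples (colnames = sample ids).
#' @param samples Data frame with columns `sample_id`, `assay` (`"RIP"`
#'   or `"totalRNA"`), `condition` (`"control"` or `"mimic"`),
#'   `cell_line`, `replicate`; one row per column of `counts`.
#' @return An object of class `"rip_counts"` with elements `counts`,
#'   `samples` (tibble) and `totals` (per-sample assigned-read totals,
#'   the column sums).
#' @export
rip_counts <- function(counts, samples) {
  stopifnot(is.matrix(counts), is.data.frame(samples))
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "assay", "condition", "cell_line", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(colnames(counts), samples$sample_id) ||
      ncol(counts) != nrow(samples)) {
    stop("count matrix columns and sample sheet rows must match one-to-one",
         call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(samples[, c("assay", "condition", "cell_line", "replicate")])) {
    stop("(assay, condition, cell_line, replicate) must be unique per sample",
         call. = FALSE)
  }
  if (!all(samples$assay %in% c("RIP", "totalRNA"))) {
    stop('assay must be "RIP" or "totalRNA"', call. = FALSE)
  }
  if (!all(samples$condition %in% c("control", "mimic"))) {
    stop('condition must be "control" or "mimic"', call. = FALSE)
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, samples = samples, totals = colSums(counts)),
    class = "rip_counts"
  )
}

#' @export
print.rip_counts <- function(x, ...) {
  cat("<rip_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  print(dplyr::count(x$samples, .data$cell_line, .data$assay, .data$condition))
  invisible(x)
}

#' @rdname rip_counts
#' @param x An `rip_counts` object.
#' @export
dim.rip_counts <- function(x) dim(x$counts)

#' Genes expressed in a cell line
#'
#' The expressed-gene background used for enrichment testing: genes with
#' at least `min_count` reads in at least one sample of the given cell
#' line (any assay, any condition).
#'
#' @param counts An [rip_counts()] object.
#' @param cell_line Cell line name as in the sample sheet.
#' @param min_count Minimum read count (default 1).
#' @return Character vector of gene ids.
#' @export
expressed_background <- function(counts, cell_line, min_count = 1L) {
  stopifnot(inherits(counts, "rip_counts"), min_count >= 1)
  ids <- counts$samples$sample_id[counts$samples$cell_line == cell_line]
  if (!length(ids)) {
    stop("unknown cell line: ", cell_line, call. = FALSE)
  }
  sub <- counts$counts[, ids, drop = FALSE]
  rownames(sub)[apply(sub >= min_count, 1, any)]
}

#' Read a gene annotation from GTF
#'
#' Imports exon records from a GTF file (via rtracklayer) and converts
#' them to the package's 0-based half-open exon table.
#'
#' @param path GTF file with `gene_id` and `transcript_id` attributes.
#' @return Tibble with columns `gene_id`, `isoform_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @export
read_gtf_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  tibble::tibble(
    gene_id = S4Vectors::mcols(gr)$gene_id,
    isoform_id = S4Vectors::mcols(gr)$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read aligned-read intervals from BED
#'
#' @param path BED file (first six columns honoured).
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open, as in BED itself).
#' @export
read_bed_alignments <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read and write count matrices as TSV
#'
#' `write_count_matrix()` writes two TSV files: the gene-by-sample count
#' table (first column `gene_id`, then one column per sample) and the
#' sample sheet. `read_count_matrix()` reads them back into an
#' [rip_counts()] object.
#'
#' @param counts An [rip_counts()] object.
#' @param counts_path,samples_path TSV file paths.
#' @return `read_count_matrix()` returns an [rip_counts()] object;
#'   `write_count_matrix()` returns its input invisibly.
#' @export
write_count_matrix <- function(counts, counts_path, samples_path) {
  stopifnot(inherits(counts, "rip_counts"))
  tbl <- tibble::as_tibble(counts$counts, rownames = "gene_id")
  readr::write_tsv(tbl, counts_path)
  readr::write_tsv(counts$samples, samples_path)
  invisible(counts)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tbl <- readr::read_tsv(counts_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  rip_counts(m, samples)
}
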