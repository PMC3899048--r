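#' Simulation configuration for synthetic RIP-seq / RNA-seq experiments
#'
#' Bundles and validates the parameters of [simulate_counts()]. The
#' generative model mirrors the biology being assayed: transfected miRNA
#' mimics displace PABP from target mRNAs (reducing their representation
#' in the immunoprecipitated library) and destabilise them (reducing
#' their representation in the total-RNA library), so the relative
#' representation of a planted target drops under mimic treatment and
#' drops more strongly in the RIP assay.
#'
#' @param n_genes Number of genes.
#' @param n_targets Number of planted miRNA targets (`<= n_genes`).
#' @param baseline_mu,baseline_sigma Log-normal parameters of relative
#'   gene abundance (natural-log scale).
#' @param rip_effect Extra fold reduction (> = 1) of a target's RIP
#'   association in mimic samples, on top of `rna_effect`.
#' @param rna_effect Fold reduction (>= 1) of a target's abundance in
#'   mimic samples. Requires `rip_effect >= 1` and `rna_effect >= 1`
#'   (displacement at least as strong as decay: the combined RIP-assay
#'   effect is `rna_effect * rip_effect`).
#' @param reads_per_sample Sequencing depth per library.
#' @param n_replicates Replicates per (assay, condition) combination.
#' @param overdispersion Variance of a mean-1 gamma jitter applied to
#'   each replicate's gene probabilities; 0 (the default) gives pure
#'   multinomial sampling at fixed depth, the null model of the
#'   contingency-table construction.
#' @param cell_lines Character vector of cell-line names to simulate.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 5000, n_targets = 250,
                       baseline_mu = 0, baseline_sigma = 1,
                       rip_effect = 1.6, rna_effect = 2.5,
                       reads_per_sample = 5e6, n_replicates = 2,
                       overdispersion = 0, cell_lines = "U251") {
  cfg <- list(
    n_genes = as.integer(n_genes), n_targets = as.integer(n_targets),
    baseline_mu = baseline_mu, baseline_sigma = baseline_sigma,
    rip_effect = rip_effect, rna_effect = rna_effect,
    reads_per_sample = as.integer(reads_per_sample),
    n_replicates = as.integer(n_replicates),
    overdispersion = overdispersion, cell_lines = cell_lines
  )
  problems <- character()
  if (cfg$n_genes < 1) problems <- c(problems, "n_genes must be >= 1")
  if (cfg$n_targets < 0 || cfg$n_targets > cfg$n_genes) {
    problems <- c(problems, "n_targets must lie in [0, n_genes]")
  }
  if (cfg$rna_effect < 1 || cfg$rip_effect < 1) {
    problems <- c(problems, "rip_effect and rna_effect must be >= 1")
  }
  if (cfg$reads_per_sample <= 0) {
    problems <- c(problems, "reads_per_sample must be positive")
  }
  if (cfg$n_replicates < 1) problems <- c(problems, "n_replicates must be >= 1")
  if (cfg$overdispersion < 0) {
    problems <- c(problems, "overdispersion must be non-negative")
  }
  if (cfg$baseline_sigma < 0) {
    problems <- c(problems, "baseline_sigma must be non-negative")
  }
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# run expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single integer seed is required", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a RIP-seq / RNA-seq count experiment with planted targets
#'
#' Draws, for every sample, `reads_per_sample` reads multinomially over
#' genes with probabilities proportional to `baseline_i * effect_i`,
#' where the effect is 1 for control samples and non-targets,
#' `1 / rna_effect` for targets in mimic total-RNA samples and
#' `1 / (rna_effect * rip_effect)` for targets in mimic RIP samples.
#' With `overdispersion > 0` each replicate's probabilities are jittered
#' by independent mean-1 gamma factors of that variance before
#' renormalisation. Identical `(config, seed)` gives identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory; generators hold no global state).
#' @return A list: `counts` (an [rip_counts()] object) and `truth` (a
#'   tibble `gene_id`, `is_target`, `rip_effect`, `rna_effect` giving the
#'   planted per-gene effects).
#' @export
simulate_counts <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
    baseline <- stats::rlnorm(config$n_genes, config$baseline_mu,
                              config$baseline_sigma)
    is_target <- seq_len(config$n_genes) <= config$n_targets
    truth <- tibble::tibble(
      gene_id = gene_ids,
      is_target = is_target,
      rip_effect = ifelse(is_target, config$rip_effect, 1),
      rna_effect = ifelse(is_target, config$rna_effect, 1)
    )

    samples <- tidyr::expand_grid(
      cell_line = config$cell_lines,
      assay = c("RIP", "totalRNA"),
      condition = c("control", "mimic"),
      replicate = seq_len(config$n_replicates)
    ) |>
      dplyr::mutate(sample_id = paste(.data$cell_line, .data$assay,
                                      .data$condition, .data$replicate,
                                      sep = "_")) |>
      dplyr::select("sample_id", "assay", "condition", "cell_line", "replicate")

    m <- matrix(0L, nrow = config$n_genes, ncol = nrow(samples),
                dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      eff <- rep(1, config$n_genes)
      if (samples$condition[j] == "mimic") {
        eff[is_target] <- if (samples$assay[j] == "RIP") {
          1 / (config$rna_effect * config$rip_effect)
        } else {
          1 / config$rna_effect
        }
      }
      prob <- baseline * eff
      if (config$overdispersion > 0) {
        shape <- 1 / config$overdispersion
        prob <- prob * stats::rgamma(config$n_genes, shape = shape,
                                     rate = shape)
      }
      m[, j] <- stats::rmultinom(1, size = config$reads_per_sample,
                                 prob = prob)[, 1]
    }
    list(counts = rip_counts(m, samples), truth = truth)
  })
}

#' Simulate miRNA target-prediction catalogs
#'
#' Emulates prediction tools (TargetScan / miRanda / PicTar style) for a
#' focal miRNA and, optionally, for additional miRNAs with a controlled
#' shared-target structure. Each tool annotates each true target of the
#' focal miRNA with probability `sensitivity[tool]` and each non-target
#' with probability `false_rate[tool]`. For each additional miRNA and
#' tool, every gene the tool annotated for the focal miRNA is shared with
#' probability `shared_fraction` (independently per miRNA), and
#' non-annotated genes are annotated at the tool's `false_rate` so the
#' extra catalogs have realistic size.
#'
#' @param truth Truth tibble from [simulate_counts()] (columns `gene_id`,
#'   `is_target`).
#' @param tools Character vector of tool names.
#' @param sensitivity,false_rate Per-tool probabilities, recycled to
#'   `length(tools)`.
#' @param mirna Name of the focal miRNA (default `"miR-137"`).
#' @param other_mirnas Character vector of additional miRNA names (may be
#'   empty).
#' @param shared_fraction Probability that an annotated focal-miRNA
#'   target is also annotated for an additional miRNA.
#' @param seed Integer seed.
#' @return A prediction catalog: tibble with columns `tool`, `mirna`,
#'   `gene_id` (one row per predicted gene per tool per miRNA).
#' @export
simulate_predictions <- function(truth, tools = c("TargetScan", "miRanda", "PicTar"),
                                 sensitivity = 0.8, false_rate = 0.05,
                                 mirna = "miR-137", other_mirnas = character(),
                                 shared_fraction = 0.3, seed) {
  probs <- c(sensitivity, false_rate, shared_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("sensitivity, false_rate and shared_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  sensitivity <- rep_len(sensitivity, length(tools))
  false_rate <- rep_len(false_rate, length(tools))
  with_seed(seed, {
    out <- list()
    for (i in seq_along(tools)) {
      p_annot <- ifelse(truth$is_target, sensitivity[i], false_rate[i])
      annotated <- stats::runif(nrow(truth)) < p_annot
      out[[length(out) + 1]] <- tibble::tibble(
        tool = tools[i], mirna = mirna,
        gene_id = truth$gene_id[annotated]
      )
      for (om in other_mirnas) {
        shared <- annotated & stats::runif(nrow(truth)) < shared_fraction
        extra <- !annotated & stats::runif(nrow(truth)) < false_rate[i]
        out[[length(out) + 1]] <- tibble::tibble(
          tool = tools[i], mirna = om,
          gene_id = truth$gene_id[shared | extra]
        )
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate a gene annotation with reads of known provenance
#'
#' Builds disjoint multi-isoform gene models on one synthetic chromosome
#' and places reads uniformly within chosen genes' super-transcript
#' blocks, returning the exact expected per-gene counts. Used to exercise
#' the isoform-collapsing and read-assignment code against a planted
#' truth.
#'
#' @param n_genes Number of genes.
#' @param n_isoforms Isoforms per gene.
#' @param reads_per_gene Reads placed inside each gene.
#' @param read_length Read length in bases.
#' @param gene_length Exonic span allotted to each gene.
#' @param gap Intergenic gap in bases (set small to provoke boundary
#'   cases deliberately).
#' @param seed Integer seed.
#' @return A list: `annotation` (exon tibble), `alignments` (read
#'   interval tibble), `expected` (tibble `gene_id`, `count`).
#' @export
simulate_annotation_and_reads <- function(n_genes = 10, n_isoforms = 3,
                                          reads_per_gene = 100,
                                          read_length = 36,
                                          gene_length = 2000, gap = 1000,
                                          seed) {
  stopifnot(n_genes >= 1, n_isoforms >= 1, gene_length > 2 * read_length)
  with_seed(seed, {
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    span <- gene_length + gap
    ann <- list(); reads <- list()
    for (g in seq_len(n_genes)) {
      g0 <- (g - 1) * span
      # isoforms share the gene span with overlapping exon pairs
      for (t in seq_len(n_isoforms)) {
        off <- round((t - 1) * gene_length / (2 * n_isoforms))
        mid <- g0 + round(gene_length / 2)
        ann[[length(ann) + 1]] <- tibble::tibble(
          gene_id = gene_ids[g],
          isoform_id = paste0(gene_ids[g], ".", t),
          chrom = "chrS", strand = "+",
          start = c(g0 + off, mid),
          end = c(mid + 10, g0 + gene_length - off)
        )
      }
      starts <- g0 + sample.int(gene_length - read_length, reads_per_gene,
                                replace = TRUE) - 1L
      reads[[g]] <- tibble::tibble(
        chrom = "chrS", start = starts, end = starts + read_length,
        strand = "+"
      )
    }
    list(
      annotation = dplyr::bind_rows(ann),
      alignments = dplyr::bind_rows(reads),
      expected = tibble::tibble(gene_id = gene_ids,
                                count = as.integer(reads_per_gene))
    )
  })
}

#' Simulate tumor expression z-scores with planted miRNA coupling
#'
#' Generates a gene-by-sample z-score matrix (expression relative to
#' normal tissue) plus a per-sample miRNA z-score vector. Each sample
#' carries a latent miRNA activity `a_s ~ N(0, 1)`; the miRNA z-score is
#' `-mir_shift + a_s` and each planted target gene's z-score is
#' `target_shift - coupling * a_s + noise_sd * N(0, 1)`. Non-target
#' genes are pure standard normal. Positive `coupling` therefore plants a
#' negative miRNA-target correlation, and positive `mir_shift` /
#' `target_shift` plant the down-regulated-miRNA / up-regulated-target
#' pattern seen in tumors.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_targets Number of planted target genes.
#' @param target_shift Mean z-score shift of target genes.
#' @param mir_shift Downward shift of the miRNA z-scores.
#' @param coupling Strength in `[0, 1]` of the planted anti-correlation.
#' @param noise_sd Standard deviation of the independent gene noise
#'   (default 1).
#' @param subtypes Character vector of subtype labels cycled over samples.
#' @param seed Integer seed.
#' @return A list: `zscores` (a `zscore_experiment`: `z` matrix plus
#'   `samples` tibble with subtype labels), `mir_z` (named numeric vector
#'   over samples), `truth` (tibble `gene_id`, `is_target`).
#' @export
simulate_zscores <- function(n_genes = 595, n_samples = 261,
                             n_targets = n_genes, target_shift = 0.5,
                             mir_shift = 1, coupling = 0.5, noise_sd = 1,
                             subtypes = c("astrocytic", "neural",
                                          "neuromesenchymal", "oligoneural",
                                          "radial_glial"),
                             seed) {
  stopifnot(n_targets <= n_genes, coupling >= 0, coupling <= 1, noise_sd >= 0)
  with_seed(seed, {
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    sample_ids <- sprintf("tumor%03d", seq_len(n_samples))
    activity <- stats::rnorm(n_samples)
    mir_z <- stats::setNames(-mir_shift + activity, sample_ids)
    is_target <- seq_len(n_genes) <= n_targets
    z <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(gene_ids, sample_ids))
    if (any(is_target)) {
      nt <- sum(is_target)
      noise <- matrix(stats::rnorm(nt * n_samples, sd = noise_sd),
                      nt, n_samples)
      z[is_target, ] <- target_shift -
        coupling * matrix(activity, nt, n_samples, byrow = TRUE) + noise
    }
    samples <- tibble::tibble(
      sample_id = sample_ids,
      subtype = rep_len(subtypes, n_samples)
    )
    list(
      zscores = zscore_experiment(z, samples),
      mir_z = mir_z,
      truth = tibble::tibble(gene_id = gene_ids, is_target = is_target)
    )
  })
}

#' Write the planted truth table as TSV
#'
#' @param truth Truth tibble from [simulate_counts()].
#' @param path Output TSV.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(truth)
}
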