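#' Read a pipeline run configuration from YAML
#'
#' The configuration names the inputs (count matrix + sample sheet, or a
#' simulation block; optional prediction-catalog manifest; optional
#' z-score matrix + subtype sheet), the thresholds, the seed and the
#' output directory. Missing thresholds fall back to the canonical
#' defaults (`or_min = 2`, `q_max = 0.001`, `min_count = 1`,
#' `z_thresholds = c(2, 3, 4, 5)`).
#'
#' @param path YAML file.
#' @return A validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A named list with the same structure as the YAML file
#'   (programmatic alternative to a file on disk).
#' @export
as_run_config <- function(config) {
  defaults <- list(
    or_min = 2, q_max = 0.001, min_count = 1,
    z_thresholds = c(2, 3, 4, 5),
    cor_cutoffs = seq(0, 0.5, by = 0.1),
    mirna = "miR-137"
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$out_dir)) {
    stop("config error: out_dir is required", call. = FALSE)
  }
  has_counts <- !is.null(config$counts_path) && !is.null(config$samples_path)
  has_sim <- !is.null(config$simulate)
  if (!has_counts && !has_sim) {
    stop("config error: provide counts_path+samples_path or a simulate block",
         call. = FALSE)
  }
  if (has_sim && is.null(config$seed)) {
    stop("config error: a seed is required whenever simulation is invoked",
         call. = FALSE)
  }
  for (p in c("counts_path", "samples_path", "z_path", "z_samples_path",
              "mir_z_path", "catalog_manifest")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("config error: file not found: ", config[[p]], call. = FALSE)
    }
  }
  if (config$or_min <= 0 || config$q_max <= 0 || config$min_count < 1 ||
      any(config$z_thresholds <= 0)) {
    stop("config error: thresholds out of range", call. = FALSE)
  }
  structure(config, class = "run_config")
}

#' Run the full target-identification pipeline
#'
#' Executes, per cell line: differential calling in both assays
#' ([call_targets()]), assay combination, prediction annotation and
#' per-tool enrichment; then cross-cell-line combination, multi-miRNA
#' shared-target profiling, and (when a z-matrix is configured) the
#' tumor-expression stage. All stage outputs are written as TSV under
#' `out_dir`, plus a JSON run manifest recording thresholds, seed, stage
#' cardinalities and warnings. Identical config and seed give identical
#' outputs.
#'
#' @param config A `run_config` (from [read_run_config()] /
#'   [as_run_config()]).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n_warnings <- 0L
  note <- function(...) {
    message("[ripfisher] ", ...)
  }
  warn_count <- function(...) {
    n_warnings <<- n_warnings + 1L
    warning(..., call. = FALSE)
  }

  stage <- "load_counts"
  manifest <- list(
    thresholds = list(or_min = config$or_min, q_max = config$q_max,
                      min_count = config$min_count,
                      z_thresholds = config$z_thresholds),
    seed = config$seed,
    version = as.character(utils::packageVersion("ripfisher")),
    stages = list()
  )
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      note("simulating counts (seed ", config$seed, ")")
      sim_args <- config$simulate
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_counts(cfg, seed = config$seed)
      counts <- sim$counts
      truth <- sim$truth
      write_truth_table(truth, file.path(out_dir, "truth.tsv"))
    } else {
      note("loading counts from ", config$counts_path)
      counts <- read_count_matrix(config$counts_path, config$samples_path)
      truth <- NULL
    }
    manifest$stages$counts <- list(
      n_genes = nrow(counts$counts), n_samples = ncol(counts$counts)
    )

    stage <- "catalog"
    catalog <- NULL
    if (!is.null(config$catalog_manifest)) {
      manifest_tbl <- readr::read_tsv(config$catalog_manifest,
                                      show_col_types = FALSE)
      catalog <- read_prediction_catalog(manifest_tbl)
    } else if (!is.null(config$simulate) && !is.null(truth)) {
      catalog <- simulate_predictions(
        truth,
        other_mirnas = c("miR-7", "miR-124", "miR-128"),
        seed = config$seed + 1
      )
    }

    stage <- "differential"
    cell_lines <- unique(counts$samples$cell_line)
    unions <- list()
    per_cell <- list()
    for (cl in cell_lines) {
      rip <- call_targets(counts, "RIP", cl, config$or_min, config$q_max)
      rna <- call_targets(counts, "totalRNA", cl, config$or_min, config$q_max)
      readr::write_tsv(rip$results,
                       file.path(out_dir, paste0("comparisons_RIP_", cl, ".tsv")))
      readr::write_tsv(rna$results,
                       file.path(out_dir, paste0("comparisons_totalRNA_", cl, ".tsv")))
      comb <- combine_assays(rip, rna)
      readr::write_tsv(comb, file.path(out_dir, paste0("called_", cl, ".tsv")))
      fc <- cross_method_fc_difference(counts, rip, rna)
      readr::write_tsv(fc, file.path(out_dir, paste0("fc_difference_", cl, ".tsv")))
      unions[[cl]] <- comb$gene_id
      cell_manifest <- list(
        n_tested = as.list(c(rip$n_tested, rna$n_tested)),
        n_called_rip = length(rip$genes),
        n_called_rna = length(rna$genes),
        n_union = nrow(comb),
        n_both = sum(comb$both),
        fc_fraction_above_1 = attr(fc, "fraction_above_1")
      )

      stage <- "enrichment"
      if (!is.null(catalog)) {
        background <- expressed_background(counts, cl, config$min_count)
        identified <- intersect(comb$gene_id, background)
        ann <- annotate_with_predictions(comb$gene_id, catalog, config$mirna)
        readr::write_tsv(ann, file.path(out_dir, paste0("predicted_", cl, ".tsv")))
        tools <- sort(unique(catalog$tool[catalog$mirna == config$mirna]))
        enr <- purrr::map_dfr(tools, function(tl) {
          enrichment_vs_tool(identified, catalog, tl, config$mirna, background)
        })
        readr::write_tsv(enr, file.path(out_dir, paste0("enrichment_", cl, ".tsv")))
        cell_manifest$n_background <- length(background)
        cell_manifest$n_predicted <- attr(ann, "n_predicted")
        cell_manifest$enrichment_min_p <- min(enr$p_value)
      }
      per_cell[[cl]] <- cell_manifest
    }
    manifest$stages$per_cell_line <- per_cell

    stage <- "combine_cell_lines"
    combined <- combine_cell_lines(unions)
    readr::write_tsv(combined, file.path(out_dir, "combined_cell_lines.tsv"))
    manifest$stages$combined <- list(
      n_combined = nrow(combined), n_shared = sum(combined$shared)
    )

    stage <- "overlap"
    if (!is.null(catalog)) {
      other <- setdiff(unique(catalog$mirna), config$mirna)
      if (length(other)) {
        ann_all <- annotate_with_predictions(combined$gene_id, catalog,
                                             config$mirna)
        focal <- ann_all$gene_id[ann_all$predicted]
        bg_all <- unique(unlist(lapply(
          cell_lines, function(cl) {
            expressed_background(counts, cl, config$min_count)
          }
        )))
        profile <- shared_target_profile(
          intersect(focal, bg_all),
          catalog_gene_sets(catalog, other), bg_all
        )
        readr::write_tsv(profile$summary, file.path(out_dir, "shared_summary.tsv"))
        readr::write_tsv(profile$pairwise, file.path(out_dir, "shared_pairwise.tsv"))
        manifest$stages$overlap <- list(
          n_focal_predicted = nrow(profile$per_gene),
          fraction_shared_all = profile$summary$fraction[
            profile$summary$n_shared == length(other)
          ]
        )
      }
    }

    stage <- "tumor"
    if (!is.null(config$z_path)) {
      zs <- read_zscore_matrix(config$z_path, config$z_samples_path)
      mir <- readr::read_tsv(config$mir_z_path, show_col_types = FALSE)
      mir_z <- stats::setNames(mir[[2]], mir[[1]])
      bias <- directional_bias(mir_z[colnames(zs$z)])
      counts_tbl <- threshold_change_counts(zs, config$z_thresholds)
      prof <- correlation_profile(mir_z, zs, config$cor_cutoffs)
      readr::write_tsv(bias, file.path(out_dir, "mir_directional_bias.tsv"))
      readr::write_tsv(counts_tbl, file.path(out_dir, "threshold_counts.tsv"))
      readr::write_tsv(prof$by_cutoff, file.path(out_dir, "correlation_profile.tsv"))
      manifest$stages$tumor <- list(
        mir_p_value = bias$p_value,
        mir_proportion_down = bias$proportion_down,
        n_cor_excluded = prof$n_excluded
      )
    } else {
      note("no z-matrix configured; tumor stage skipped")
      manifest$stages$tumor <- "skipped"
    }
    manifest
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  result$n_warnings <- n_warnings
  jsonlite::write_json(result, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
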