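#' Build and validate a pipeline configuration
#'
#' @param bundle_dir Directory holding a fixture bundle (see
#'   [write_fixture_bundle()]) or equivalently named real inputs.
#' @param out_dir Output directory for result tables and the manifest.
#' @param alpha Gate level used by every differential stage.
#' @param promoter_window Promoter half-width (bp).
#' @param n_perm GSEA permutations.
#' @param seed Top-level seed; per-stage sub-seeds are derived from it.
#' @param rules Trend rule table (default [default_trend_rules()]).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(bundle_dir, out_dir, alpha = 0.05,
                            promoter_window = 3000, n_perm = 200, seed = 1,
                            rules = default_trend_rules()) {
  cfg <- list(bundle_dir = bundle_dir, out_dir = out_dir, alpha = alpha,
              promoter_window = promoter_window, n_perm = n_perm, seed = seed,
              rules = validate_trend_rules(rules))
  need <- c("sample_sheet.csv", "bulk_counts.tsv", "gene_models.bed12",
            "chrom_sample_sheet.csv", "promoter_counts.tsv", "other_counts.tsv",
            "gene_sets.gmt", "sc_counts.tsv", "sc_cells.tsv", "sc_gene_sets.gmt")
  missing <- need[!file.exists(file.path(bundle_dir, need))]
  if (length(missing)) {
    abort(paste0("bundle is missing: ", paste(missing, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline on a fixture bundle
#'
#' Executes, in dependency order: gated differential comparisons of the
#' bulk counts (all four contrasts per lobe), trend assignment with shared
#' and lobe-specific Rein02 sets, spike-in-calibrated promoter/other
#' differential testing with shift typing, peak annotation with
#' promoter-fraction summaries, a-DEG concordance against the promoter
#' results, preranked GSEA of each rankable comparison, and the single-cell
#' QC / stratification / gated-t stage. All tables are written as
#' deterministic TSVs plus a `manifest.json` echoing seeds and parameters;
#' identical config and bundle give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bd <- config$bundle_dir
  res <- list()

  # --- de ---
  samples <- read_sample_sheet(file.path(bd, "sample_sheet.csv"))
  counts <- read_count_matrix(file.path(bd, "bulk_counts.tsv"), samples)
  rna <- run_all_comparisons(counts, samples, alpha = config$alpha)
  write_results_tsv(rna, file.path(config$out_dir, "rna_comparisons.tsv"))
  stage_log("de", "%d genes x %d comparison tables", length(unique(rna$gene_id)),
            nrow(dplyr::distinct(rna, .data$comparison, .data$lobe)))
  res$rna <- rna

  # --- trend ---
  trends <- assign_trends(rna, config$rules)
  write_results_tsv(trends, file.path(config$out_dir, "trend_assignments.tsv"))
  rein02 <- split(trends$gene_id[trends$label == "Rein02"],
                  trends$lobe[trends$label == "Rein02"])
  lobes_present <- sort(unique(trends$lobe))
  rein02 <- purrr::map(setNames(lobes_present, lobes_present),
                       function(lb) rein02[[lb]] %||% character())
  ss <- shared_specific(rein02)
  readr::write_lines(ss$shared, file.path(config$out_dir, "rein02_shared.txt"))
  write_results_tsv(ss$classes, file.path(config$out_dir, "rein02_classes.tsv"))
  stage_log("trend", "%d Rein02 genes shared by all lobes", length(ss$shared))
  res$trends <- trends; res$rein02 <- ss

  # --- chrom ---
  chrom_samples <- read_sample_sheet(file.path(bd, "chrom_sample_sheet.csv"))
  pc <- read_count_matrix(file.path(bd, "promoter_counts.tsv"), chrom_samples)
  oc <- read_count_matrix(file.path(bd, "other_counts.tsv"), chrom_samples)
  chrom_groups <- unique(chrom_samples$group)
  chrom_lobe <- unique(chrom_samples$lobe)[1]
  spec <- comparison_spec("M", "G", chrom_lobe)
  shifts <- shift_typing(pc, oc, chrom_samples, spec, alpha = config$alpha)
  write_results_tsv(shifts, file.path(config$out_dir, "shift_types.tsv"))
  models <- read_gene_models_bed12(file.path(bd, "gene_models.bed12"))
  peak_files <- sort(list.files(file.path(bd, "peaks"), full.names = TRUE))
  peaks <- purrr::map(peak_files, function(f) {
    read_bed_peaks(f, sub("\\.bed$", "", basename(f)))
  }) |> list_rbind()
  annotated <- annotate_peaks(peaks, models, promoter_window = config$promoter_window)
  write_results_tsv(dplyr::mutate(annotated, category = as.character(.data$category)),
                    file.path(config$out_dir, "annotated_peaks.tsv"))
  sfac <- spikein_factors(setNames(chrom_samples$spike_in_reads,
                                   chrom_samples$sample_id))
  region <- aggregate_region_signal(annotated, sfac)
  write_results_tsv(region, file.path(config$out_dir, "region_signal.tsv"))
  pf <- promoter_fraction(region)
  write_results_tsv(pf, file.path(config$out_dir, "promoter_fraction.tsv"))
  prom_res <- run_comparison(pc, chrom_samples, spec, alpha = config$alpha,
                             sf = setNames(1 / sfac, chrom_samples$sample_id))
  write_results_tsv(as_tibble(prom_res),
                    file.path(config$out_dir, "promoter_comparisons.tsv"))
  stage_log("chrom", "%d peaks annotated; mean promoter fraction %.3f",
            nrow(annotated), mean(pf$promoter_fraction))
  res$shifts <- shifts; res$region <- region; res$promoter_fraction <- pf
  res$prom_res <- prom_res

  # --- adeg ---
  rna_match <- rna |>
    dplyr::filter(.data$comparison == spec$label, .data$lobe == chrom_lobe)
  adegs <- find_adegs(rna_match, as_tibble(prom_res))
  write_results_tsv(adegs, file.path(config$out_dir, "adegs.tsv"))
  ov <- overlap_with_labels(adegs, c(list(shared = ss$shared), ss$specific))
  write_results_tsv(ov$counts, file.path(config$out_dir, "adeg_overlaps.tsv"))
  stage_log("adeg", "%d a-DEGs in %s/%s", nrow(adegs), spec$label, chrom_lobe)
  res$adegs <- adegs; res$adeg_overlaps <- ov

  # --- enrich (bulk GSEA) ---
  sets <- read_gmt(file.path(bd, "gene_sets.gmt"))
  nes <- rna |>
    dplyr::group_split(.data$comparison, .data$lobe) |>
    purrr::map(function(chunk) {
      if (sum(chunk$g != 0) < 2) return(NULL)
      r <- rank_genes(chunk)
      out <- as_tibble(gsea_nes(r, sets, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, paste0("nes_", chunk$comparison[1], "_", chunk$lobe[1]))))
      out$comparison <- chunk$comparison[1]
      out$lobe <- chunk$lobe[1]
      out
    }) |> list_rbind()
  write_results_tsv(nes, file.path(config$out_dir, "nes_table.tsv"))
  stage_log("enrich", "%d NES rows", nrow(nes))
  res$nes <- nes

  # --- single cell ---
  sc_cells <- readr::read_tsv(file.path(bd, "sc_cells.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  sc_counts <- read_count_matrix(file.path(bd, "sc_counts.tsv"),
                                 tibble(sample_id = sc_cells$cell_id))
  sc_cells <- qc_filter(sc_cells)
  keep <- !sc_cells$qc_flagged
  kept_counts <- sc_counts[, c("gene_id", sc_cells$cell_id[keep])]
  kept_cells <- sc_cells[keep, ]
  sig <- signature_scores(kept_counts, default_signature_genes())
  strata <- stratify(sig)
  sc_sets <- read_gmt(file.path(bd, "sc_gene_sets.gmt"))
  cell_scores <- score_cells(kept_counts, sc_sets)
  gt <- gated_t_matrix(cell_scores, strata, kept_cells$cell_type,
                       alpha = config$alpha)
  write_results_tsv(gt, file.path(config$out_dir, "gated_t.tsv"))
  write_results_tsv(dplyr::bind_cols(kept_cells[, c("cell_id", "cell_type")],
                                     tibble(signature_score = unname(sig),
                                            stratum = strata)),
                    file.path(config$out_dir, "sc_strata.tsv"))
  stage_log("sc", "%d/%d cells kept; %d gated-t rows nonzero",
            sum(keep), nrow(sc_cells), sum(gt$gated_t != 0, na.rm = TRUE))
  res$gated_t <- gt; res$strata <- strata; res$sc_cells <- sc_cells

  manifest <- list(
    package = "lobeomics",
    version = as.character(utils::packageVersion("lobeomics")),
    seed = config$seed,
    alpha = config$alpha,
    promoter_window = config$promoter_window,
    n_perm = config$n_perm,
    bundle_dir = basename(config$bundle_dir),
    outputs = sort(list.files(config$out_dir))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
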