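#' Canonical group offsets for a planted trend label
#'
#' Maps each trend label to the log2 offsets of the four groups (C, G, P, M)
#' that realize its canonical sign pattern, derived from — and asserted
#' against — the active trend rule table, so the generator and the
#' classifier share one source of truth.
#'
#' @param labels Character vector of labels in `NE`, `Rein01`, `Rein02`,
#'   `SR`, `Whip01`.
#' @param effect Absolute log2 effect size (> 0 unless all labels are NE).
#' @param sign Per-gene direction of the disease trend (+1 or -1), recycled.
#' @param rules Trend rule table used for the consistency assertion.
#' @return Tibble: `label`, columns `C`, `G`, `P`, `M` of log2 offsets.
#' @export
trend_offsets <- function(labels, effect, sign = 1L,
                          rules = default_trend_rules()) {
  sign <- rep_len(sign, length(labels))
  base <- list(
    NE     = c(C = 0, G = 0, P = 0, M = 0),
    Rein01 = c(C = 0, G = 1, P = 0, M = 0),
    Rein02 = c(C = 0, G = 1, P = 1, M = 0),
    SR     = c(C = 0, G = 1, P = 0, M = 1),
    Whip01 = c(C = 0, G = 1, P = 1, M = 2)
  )
  bad <- setdiff(unique(labels), names(base))
  if (length(bad)) abort(paste0("unknown trend label(s): ", paste(bad, collapse = ", ")))
  off <- purrr::map2(labels, sign, function(lb, sg) base[[lb]] * sg * effect) |>
    do.call(what = rbind)
  out <- dplyr::bind_cols(tibble(label = labels), as_tibble(off))
  # single-source-of-truth check: the implied sign pattern classifies back
  pat <- tibble(s_GvC = as.integer(sign(out$G - out$C)),
                s_MvG = as.integer(sign(out$M - out$G)),
                s_PvG = as.integer(sign(out$P - out$G)),
                s_MvP = as.integer(sign(out$M - out$P)))
  stopifnot(identical(classify_trend(pat, rules), out$label))
  out
}

#' Simulate a four-group, five-lobe bulk count dataset
#'
#' Counts are negative binomial with variance `mu + phi mu^2`. Per-gene
#' baseline means are drawn log-uniformly over `[depth/16, depth*16]`
#' (geometric mean `depth`); per-sample size factors are log-uniform in
#' `[0.5, 2]` to exercise normalization. Trend labels are planted per gene
#' via [trend_offsets()], identically across lobes, with a random direction.
#'
#' @param n_genes Number of genes.
#' @param n_reps_per_cell Replicates per (group, lobe) cell (>= 2).
#' @param effect_log2fc Planted absolute log2 effect (> 0).
#' @param dispersion NB dispersion phi.
#' @param depth Per-gene baseline mean scale.
#' @param label_proportions Named proportions over the five labels (sum 1).
#' @param lobes Lobes to simulate.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List: `counts` (tibble), `samples` (sample sheet tibble),
#'   `truth` (tibble: `gene_id`, `label`, `sign`, `mu`, `phi`).
#' @export
sim_bulk <- function(n_genes = 1000, n_reps_per_cell = 3, effect_log2fc = 2.5,
                     dispersion = 0.1, depth = 1e4,
                     label_proportions = c(NE = 0.6, Rein01 = 0.1, Rein02 = 0.1,
                                           SR = 0.1, Whip01 = 0.1),
                     lobes = LOBES, seed = 1) {
  if (n_reps_per_cell < 2) abort("n_reps_per_cell must be >= 2")
  check_scalar_number(effect_log2fc, "effect_log2fc", positive = TRUE)
  if (abs(sum(label_proportions) - 1) > 1e-8) abort("label_proportions must sum to 1")
  set.seed(derive_seed(seed, "bulk"))
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  n_lab <- round(label_proportions * n_genes)
  n_lab[1] <- n_genes - sum(n_lab[-1])
  labels <- sample(rep(names(n_lab), times = n_lab))
  sgn <- ifelse(labels == "NE", 1L, sample(c(-1L, 1L), n_genes, replace = TRUE))
  off <- trend_offsets(labels, effect_log2fc, sgn)
  mu <- depth * 2^runif(n_genes, -4, 4)
  samples <- tidyr::expand_grid(group = GROUPS, lobe = lobes,
                                replicate = seq_len(n_reps_per_cell)) |>
    dplyr::mutate(sample_id = paste(.data$group, .data$lobe, .data$replicate, sep = "_")) |>
    dplyr::select("sample_id", "group", "lobe", "replicate")
  sf <- 2^runif(nrow(samples), -1, 1)
  cnt <- matrix(0, n_genes, nrow(samples), dimnames = list(gene_ids, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    g_off <- off[[samples$group[s]]]
    cnt[, s] <- rnbinom(n_genes, mu = sf[s] * mu * 2^g_off, size = 1 / dispersion)
  }
  list(counts = matrix_to_counts(cnt), samples = samples,
       truth = tibble(gene_id = gene_ids, label = labels, sign = sgn,
                      mu = mu, phi = dispersion))
}

#' Simulate non-overlapping gene models
#'
#' Genes are packed left to right along the supplied chromosomes with gaps
#' of at least `min_gap`; with `disjoint_promoters = TRUE` the gaps are
#' widened so that all promoter windows (+/- `promoter_window` around the
#' strand-aware TSS) are pairwise disjoint. Each model gets 1-3 exons and a
#' thick (CDS) region strictly inside the exon span, so UTR categories are
#' exercised.
#'
#' @param n_genes Number of genes.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param min_gap Minimum intergenic gap (bp).
#' @param span_range Gene span range (bp).
#' @param promoter_window Promoter half-width used for the disjointness
#'   guarantee.
#' @param disjoint_promoters Guarantee pairwise-disjoint promoter windows.
#' @param gene_ids Optional ids (default `GENE0001`...).
#' @param seed Seed.
#' @return Gene-model tibble (see [read_gene_models_bed12()]).
#' @export
sim_gene_models <- function(n_genes = 100, chrom_sizes = c(chr1 = 3e6, chr2 = 3e6),
                            min_gap = 1000, span_range = c(8000, 16000),
                            promoter_window = 3000, disjoint_promoters = TRUE,
                            gene_ids = NULL, seed = 1) {
  set.seed(derive_seed(seed, "models"))
  gene_ids <- gene_ids %||% sprintf("GENE%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  gap <- if (disjoint_promoters) max(min_gap, 2 * promoter_window + 2) else min_gap
  slot <- span_range[2] + gap
  capacity <- sum(chrom_sizes %/% slot)
  if (capacity < n_genes) {
    abort(sprintf("cannot pack %d genes: capacity %d at span<=%d, gap>=%d",
                  n_genes, capacity, span_range[2], gap))
  }
  rows <- vector("list", n_genes)
  ci <- 1L; cursor <- 0
  for (k in seq_len(n_genes)) {
    span <- round(runif(1, span_range[1], span_range[2]))
    while (cursor + gap + span > chrom_sizes[ci]) {
      ci <- ci + 1L
      cursor <- 0
    }
    start <- cursor + gap
    end <- start + span
    cursor <- end
    n_ex <- sample(1:3, 1)
    if (n_ex == 1) {
      exons <- cbind(start = start, end = end)
    } else {
      cuts <- sort(round(runif(2 * (n_ex - 1), start + 200, end - 200)))
      bounds <- c(start, cuts, end)
      exons <- cbind(start = bounds[seq(1, length(bounds), 2)],
                     end = bounds[seq(2, length(bounds), 2)])
      ok <- exons[, 1] < exons[, 2]
      exons <- exons[ok, , drop = FALSE]
    }
    thick_start <- exons[1, 1] + min(100, floor((exons[1, 2] - exons[1, 1]) / 2))
    thick_end <- exons[nrow(exons), 2] - min(100, floor((exons[nrow(exons), 2] - exons[nrow(exons), 1]) / 2))
    rows[[k]] <- tibble(gene_id = gene_ids[k], chrom = names(chrom_sizes)[ci],
                        start = start, end = end,
                        strand = sample(c("+", "-"), 1),
                        thick_start = thick_start, thick_end = thick_end,
                        exons = list(exons))
  }
  models <- list_rbind(rows)
  purrr::pwalk(models, function(gene_id, start, end, exons, ...) {
    validate_gene_model(gene_id, start, end, exons)
  })
  models
}

#' Simulate chromatin region signal with planted promoter shifts
#'
#' For two contrasted groups (default disease `G` vs treatment `M`), each
#' gene gets promoter and other-region NB counts around a baseline total,
#' with the promoter share set by `promoter_fraction_baseline`. Planted
#' `Type1` genes gain promoter signal and lose other-region signal in the
#' numerator group (`Type2` mirrored, `None` unchanged). Per-sample library
#' scale is log-uniform in `[0.5, 2]` and spike-in reads are Poisson with
#' mean proportional to the same scale, so spike-in calibration recovers
#' comparable signal.
#'
#' @param gene_models Gene-model tibble; one signal unit per gene.
#' @param n_samples_per_group Replicates per group (>= 2).
#' @param shift_proportions Named proportions over `Type1`, `Type2`, `None`.
#' @param promoter_fraction_baseline Baseline promoter share in (0, 1).
#' @param spike_mean Expected spike-in reads at unit library scale (> 0).
#' @param effect_log2fc Planted |log2 shift| applied up on one region and
#'   down on the other.
#' @param depth Per-gene baseline total mean.
#' @param dispersion NB dispersion.
#' @param groups Length-2: denominator then numerator group code.
#' @param lobe Lobe code recorded on the samples.
#' @param seed Seed.
#' @return List: `promoter_counts`, `other_counts` (count tibbles),
#'   `samples` (sheet with `spike_in_reads`), `peaks` (tibble, one promoter
#'   and one gene-body peak per gene per sample), `truth`.
#' @export
sim_chromatin <- function(gene_models, n_samples_per_group = 3,
                          shift_proportions = c(Type1 = 0.1, Type2 = 0.1, None = 0.8),
                          promoter_fraction_baseline = 0.6, spike_mean = 1e4,
                          effect_log2fc = 1, depth = 1e4, dispersion = 0.01,
                          groups = c("G", "M"), lobe = "L", seed = 1) {
  if (promoter_fraction_baseline <= 0 || promoter_fraction_baseline >= 1) {
    abort("promoter_fraction_baseline must be in (0, 1)")
  }
  check_scalar_number(spike_mean, "spike_mean", positive = TRUE)
  if (n_samples_per_group < 2) abort("n_samples_per_group must be >= 2")
  if (abs(sum(shift_proportions) - 1) > 1e-8) abort("shift_proportions must sum to 1")
  set.seed(derive_seed(seed, "chromatin"))
  n_genes <- nrow(gene_models)
  gene_ids <- gene_models$gene_id
  n_typ <- round(shift_proportions * n_genes)
  n_typ["None"] <- n_genes - sum(n_typ[setdiff(names(n_typ), "None")])
  types <- sample(rep(names(n_typ), times = n_typ))
  total <- depth * 2^runif(n_genes, -2, 2)
  p_base <- promoter_fraction_baseline * total
  o_base <- (1 - promoter_fraction_baseline) * total
  d_p <- ifelse(types == "Type1", effect_log2fc, ifelse(types == "Type2", -effect_log2fc, 0))
  d_o <- -d_p
  samples <- tidyr::expand_grid(group = groups, replicate = seq_len(n_samples_per_group)) |>
    dplyr::mutate(sample_id = paste(.data$group, lobe, .data$replicate, sep = "_"),
                  lobe = lobe) |>
    dplyr::select("sample_id", "group", "lobe", "replicate")
  lib <- 2^runif(nrow(samples), -1, 1)
  samples$spike_in_reads <- rpois(nrow(samples), lib * spike_mean)
  pc <- oc <- matrix(0, n_genes, nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    boost_p <- if (samples$group[s] == groups[2]) 2^d_p else 1
    boost_o <- if (samples$group[s] == groups[2]) 2^d_o else 1
    pc[, s] <- rnbinom(n_genes, mu = lib[s] * p_base * boost_p, size = 1 / dispersion)
    oc[, s] <- rnbinom(n_genes, mu = lib[s] * o_base * boost_o, size = 1 / dispersion)
  }
  # peaks: promoter peak centered on the TSS, gene-body peak 60% of the span
  # downstream of the TSS (clear of every promoter window by construction)
  tss <- ifelse(gene_models$strand == "+", gene_models$start, gene_models$end - 1)
  dir <- ifelse(gene_models$strand == "+", 1, -1)
  body_mid <- round(tss + dir * 0.6 * (gene_models$end - gene_models$start))
  peaks <- purrr::map(seq_len(nrow(samples)), function(s) {
    tibble(chrom = rep(gene_models$chrom, 2),
           start = c(pmax(0, tss - 100), pmax(0, body_mid - 100)),
           end = c(tss + 100, body_mid + 100),
           score = c(pc[, s], oc[, s]),
           sample_id = samples$sample_id[s])
  }) |> list_rbind()
  list(promoter_counts = matrix_to_counts(pc), other_counts = matrix_to_counts(oc),
       samples = samples, peaks = peaks,
       truth = tibble(gene_id = gene_ids, shift_type = types,
                      d_promoter = d_p, d_other = d_o, total_mean = total))
}

sc_marker_sets <- function() {
  list(
    epithelial = c("Epcam", "Krt19", "Krt18", "Cdh1"),
    fibroblast = c("Dcn", "Thy1", "Col1a1", "Col1a2"),
    endothelial = c("Pecam1", "Cldn5", "Flt1", "Ramp2"),
    T = c("Cd3d", "Cd3e", "Cd3g", "Trac"),
    NK = c("Nkg7", "Gnly", "Ncam1", "Klrd1"),
    B = c("Cd79a", "Ighm", "Ighg3", "Igha2"),
    myeloid = c("Lyz", "Marco", "Cd68", "Fcgr3a"),
    mast = c("Kit", "Ms4a2")
  )
}

#' Default 16-gene treatment signature
#'
#' The myeloid / T-NK / B / epithelial response genes used as the default
#' planted signature in [sim_sc()] and as the default stratification
#' signature downstream.
#'
#' @return Character vector of 16 gene symbols.
#' @export
default_signature_genes <- function() {
  c("Fam174a", "Ifi204", "Slc7a11", "Chil3", "Capza2", "Clec5a", "Clec4a2",
    "Eif3f", "Cited2", "Crybg1", "Ndufs4", "Emb", "Blnk", "Alcam",
    "Chmp2b", "Metap2")
}

#' Simulate a single-cell expression matrix with planted strata
#'
#' Cells get a type (eight lung types with canonical markers elevated only
#' in their type), a signature stratum (`high` cells have signature genes
#' shifted up by `signature_effect_log2fc`), per-cell QC metrics, and an
#' exact planted fraction of QC outliers, each violating at least one of
#' the standard bounds (nFeature in [400, 7000], nCount in [500, 80000],
#' mito <= 15%, ribo <= 40%).
#'
#' @param n_cells Number of cells (>= 4).
#' @param type_proportions Named proportions over the eight cell types.
#' @param signature_genes Non-empty character vector (defaults to the
#'   16-gene treatment signature).
#' @param signature_effect_log2fc Planted log2 shift of signature genes in
#'   high-stratum cells (0 gives an exchangeable null).
#' @param qc_outlier_fraction Fraction of planted QC outliers in [0, 0.5).
#' @param n_background Background genes beyond markers and signature.
#' @param marker_log2fc Marker elevation in the owning type.
#' @param depth Mean count scale per gene.
#' @param seed Seed.
#' @return List: `counts` (gene x cell tibble, `gene_id` first), `cells`
#'   (tibble: `cell_id`, `cell_type`, `nFeature`, `nCount`, `pct_mito`,
#'   `pct_ribo`), `truth` (adds `stratum`, `qc_outlier`).
#' @export
sim_sc <- function(n_cells = 2000,
                   type_proportions = c(epithelial = 0.15, fibroblast = 0.1,
                                        endothelial = 0.1, T = 0.25, NK = 0.1,
                                        B = 0.1, myeloid = 0.15, mast = 0.05),
                   signature_genes = default_signature_genes(),
                   signature_effect_log2fc = 1, qc_outlier_fraction = 0.05,
                   n_background = 150, marker_log2fc = 3, depth = 5, seed = 1) {
  if (!length(signature_genes)) abort("signature_genes must be non-empty")
  if (qc_outlier_fraction < 0 || qc_outlier_fraction >= 0.5) {
    abort("qc_outlier_fraction must be in [0, 0.5)")
  }
  markers <- sc_marker_sets()
  bad <- setdiff(names(type_proportions), names(markers))
  if (length(bad)) abort(paste0("unknown cell type(s): ", paste(bad, collapse = ", ")))
  if (abs(sum(type_proportions) - 1) > 1e-8) abort("type_proportions must sum to 1")
  set.seed(derive_seed(seed, "sc"))
  genes <- unique(c(unlist(markers[names(type_proportions)]), signature_genes,
                    sprintf("Bg%03d", seq_len(n_background))))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  cell_type <- sample(names(type_proportions), n_cells, replace = TRUE,
                      prob = type_proportions)
  stratum <- sample(rep(c("high", "low"), length.out = n_cells))
  base <- depth * 2^runif(length(genes), -2, 2)
  names(base) <- genes
  lib <- 2^runif(n_cells, -0.5, 0.5)
  cnt <- matrix(0, length(genes), n_cells, dimnames = list(genes, cell_ids))
  sig_idx <- genes %in% signature_genes
  for (j in seq_len(n_cells)) {
    mu <- base
    mk <- markers[[cell_type[j]]]
    mu[mk] <- mu[mk] * 2^marker_log2fc
    if (stratum[j] == "high") mu[sig_idx] <- mu[sig_idx] * 2^signature_effect_log2fc
    cnt[, j] <- rpois(length(genes), lib[j] * mu)
  }
  n_out <- round(qc_outlier_fraction * n_cells)
  outlier <- rep(FALSE, n_cells)
  outlier[sample(n_cells, n_out)] <- TRUE
  qc <- tibble(
    cell_id = cell_ids,
    nFeature = round(runif(n_cells, 800, 5000)),
    nCount = round(runif(n_cells, 1500, 40000)),
    pct_mito = runif(n_cells, 0, 10),
    pct_ribo = runif(n_cells, 0, 30)
  )
  which_bound <- sample(6, n_cells, replace = TRUE)
  for (j in which(outlier)) {
    switch(which_bound[j],
           qc$nFeature[j] <- round(runif(1, 50, 399)),
           qc$nFeature[j] <- round(runif(1, 7001, 9000)),
           qc$nCount[j] <- round(runif(1, 100, 499)),
           qc$nCount[j] <- round(runif(1, 80001, 120000)),
           qc$pct_mito[j] <- runif(1, 16, 40),
           qc$pct_ribo[j] <- runif(1, 41, 80))
  }
  cells <- dplyr::bind_cols(tibble(cell_id = cell_ids, cell_type = cell_type), qc[, -1])
  truth <- dplyr::bind_cols(cells[, c("cell_id", "cell_type")],
                            tibble(stratum = stratum, qc_outlier = outlier))
  list(counts = matrix_to_counts(cnt), cells = cells, truth = truth)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits everything an end-to-end pipeline run needs: bulk sample sheet and
#' counts, gene models (BED12), chromatin sample sheet with spike-in reads,
#' promoter/other count tables, per-sample peak BEDs, gene sets (GMT),
#' single-cell counts and metadata, truth tables, and a JSON manifest
#' recording the seed and parameters. Identical (seed, scale) reproduce
#' identical bytes.
#'
#' @param outdir Output directory (created; must be empty unless `force`).
#' @param scale `"tiny"` (minutes of compute downstream) or `"default"`.
#' @param seed Seed.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
write_fixture_bundle <- function(outdir, scale = c("tiny", "default"),
                                 seed = 1, force = FALSE) {
  scale <- match.arg(scale)
  if (dir.exists(outdir) && length(list.files(outdir)) && !force) {
    abort(sprintf("directory '%s' is not empty; use force = TRUE", outdir))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  prm <- if (scale == "tiny") {
    list(n_genes = 120, n_reps = 3, n_chrom_genes = 60, chrom_samples = 3,
         n_cells = 300, n_background = 60, n_sets = 5, set_size = 15)
  } else {
    list(n_genes = 1000, n_reps = 3, n_chrom_genes = 200, chrom_samples = 3,
         n_cells = 2000, n_background = 150, n_sets = 10, set_size = 25)
  }
  bulk <- sim_bulk(n_genes = prm$n_genes, n_reps_per_cell = prm$n_reps, seed = seed)
  readr::write_csv(bulk$samples, file.path(outdir, "sample_sheet.csv"), progress = FALSE)
  write_count_matrix(bulk$counts, file.path(outdir, "bulk_counts.tsv"))
  write_results_tsv(bulk$truth, file.path(outdir, "bulk_truth.tsv"))

  models <- sim_gene_models(n_genes = prm$n_chrom_genes,
                            gene_ids = bulk$truth$gene_id[seq_len(prm$n_chrom_genes)],
                            seed = derive_seed(seed, "bundle_models"))
  write_gene_models_bed12(models, file.path(outdir, "gene_models.bed12"))
  chrom <- sim_chromatin(models, n_samples_per_group = prm$chrom_samples,
                         seed = derive_seed(seed, "bundle_chrom"))
  readr::write_csv(chrom$samples, file.path(outdir, "chrom_sample_sheet.csv"), progress = FALSE)
  write_count_matrix(chrom$promoter_counts, file.path(outdir, "promoter_counts.tsv"))
  write_count_matrix(chrom$other_counts, file.path(outdir, "other_counts.tsv"))
  write_results_tsv(chrom$truth, file.path(outdir, "chrom_truth.tsv"))
  for (sid in chrom$samples$sample_id) {
    write_bed_peaks(chrom$peaks[chrom$peaks$sample_id == sid, ],
                    file.path(outdir, "peaks", paste0(sid, ".bed")))
  }

  set.seed(derive_seed(seed, "bundle_sets"))
  sets <- purrr::map(seq_len(prm$n_sets), function(k) {
    tibble(set_name = sprintf("SET%02d", k), description = "synthetic gene set",
           genes = list(sort(sample(bulk$truth$gene_id, prm$set_size))))
  }) |> list_rbind()
  write_gmt(sets, file.path(outdir, "gene_sets.gmt"))

  sc <- sim_sc(n_cells = prm$n_cells, n_background = prm$n_background, seed = seed)
  write_count_matrix(sc$counts, file.path(outdir, "sc_counts.tsv"))
  write_results_tsv(sc$cells, file.path(outdir, "sc_cells.tsv"))
  write_results_tsv(sc$truth, file.path(outdir, "sc_truth.tsv"))
  sc_genes <- sc$counts$gene_id
  bg <- setdiff(sc_genes, default_signature_genes())
  set.seed(derive_seed(seed, "bundle_scsets"))
  sc_sets <- dplyr::bind_rows(
    tibble(set_name = "SIGNATURE_RESPONSE", description = "contains the planted signature",
           genes = list(sort(default_signature_genes()))),
    tibble(set_name = "NEUTRAL_A", description = "disjoint from the signature",
           genes = list(sort(sample(bg, 20)))),
    tibble(set_name = "NEUTRAL_B", description = "disjoint from the signature",
           genes = list(sort(sample(bg, 20))))
  )
  write_gmt(sc_sets, file.path(outdir, "sc_gene_sets.gmt"))

  manifest <- list(generator = "lobeomics::write_fixture_bundle",
                   version = as.character(utils::packageVersion("lobeomics")),
                   scale = scale, seed = seed, parameters = prm)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
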