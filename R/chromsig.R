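FEATURE_LEVELS <- c("Promoter", "FivePrimeUTR", "ThreePrimeUTR", "Exon",
                    "Intron", "Downstream", "DistalIntergenic")

#' Spike-in calibration factors
#'
#' Per-sample scale factors `C / n` from reads mapping to the exogenous
#' spike-in genome; multiplying each sample's signal by its factor equalizes
#' the expected spike-derived signal across libraries.
#'
#' @param spike_in_reads Named (or plain) vector of per-sample spike counts.
#' @param c0 Calibration constant.
#' @return Per-sample factors.
#' @export
spikein_factors <- function(spike_in_reads, c0 = 10000) {
  check_scalar_number(c0, "c0", positive = TRUE)
  bad <- which(is.na(spike_in_reads) | spike_in_reads <= 0)
  if (length(bad)) {
    nm <- names(spike_in_reads)[bad[1]] %||% as.character(bad[1])
    abort(sprintf("sample %s has no spike-in reads; cannot calibrate", nm))
  }
  c0 / spike_in_reads
}

# strand-aware TSS/TES positions for a gene-model tibble
model_tss <- function(models) ifelse(models$strand == "+", models$start, models$end - 1)
model_tes <- function(models) ifelse(models$strand == "+", models$end - 1, models$start)

# category of a single genomic position against one gene model (scalar
# fields, exons as a 2-column matrix); returns a level index into
# FEATURE_LEVELS or NA when the position touches nothing
position_category <- function(pos, tss, start, end, strand, thick_start,
                              thick_end, exons, promoter_window,
                              downstream_window) {
  if (abs(pos - tss) <= promoter_window) return(1L)
  in_exon <- any(pos >= exons[, 1] & pos < exons[, 2])
  if (in_exon) {
    if (thick_start < thick_end) {
      before_cds <- pos < thick_start
      after_cds <- pos >= thick_end
      if (strand == "+") {
        if (before_cds) return(2L)
        if (after_cds) return(3L)
      } else {
        if (after_cds) return(2L)
        if (before_cds) return(3L)
      }
    }
    return(4L)
  }
  if (pos >= start && pos < end) return(5L)
  tes <- if (strand == "+") end - 1 else start
  if (strand == "+" && pos > tes && pos <= tes + downstream_window) return(6L)
  if (strand == "-" && pos < tes && pos >= tes - downstream_window) return(6L)
  NA_integer_
}

#' Annotate peaks to genomic features with promoter precedence
#'
#' Each peak is assigned by its midpoint to exactly one category with the
#' fixed precedence Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream >
#' DistalIntergenic: if the midpoint falls in any gene's promoter window
#' (+/- `promoter_window` around the strand-aware TSS) the peak is Promoter
#' regardless of other overlaps, and so on down the list. Ties within a
#' category go to the gene with the nearest TSS (then lexicographic
#' gene_id). Distal peaks report the nearest-TSS gene on the chromosome.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, ...).
#' @param models Gene-model tibble.
#' @param promoter_window Promoter half-width in bp.
#' @param downstream_window Downstream window length in bp.
#' @return `peaks` plus `category` (factor), `gene_id`, `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, models, promoter_window = 3000,
                           downstream_window = 3000) {
  mids <- floor((peaks$start + peaks$end) / 2)
  n <- nrow(peaks)
  category <- rep("DistalIntergenic", n)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  models_by_chrom <- split(seq_len(nrow(models)), models$chrom)
  tss_all <- model_tss(models)
  # plain vectors for the inner loop
  m_start <- models$start; m_end <- models$end; m_strand <- models$strand
  m_thick_s <- models$thick_start; m_thick_e <- models$thick_end
  m_exons <- models$exons
  for (i in seq_len(n)) {
    idx <- models_by_chrom[[peaks$chrom[i]]]
    if (is.null(idx)) {
      inform(sprintf("peak on chromosome %s absent from gene models; DistalIntergenic with no gene",
                     peaks$chrom[i]))
      next
    }
    cats <- vapply(idx, function(k) {
      position_category(mids[i], tss_all[k], m_start[k], m_end[k], m_strand[k],
                        m_thick_s[k], m_thick_e[k], m_exons[[k]],
                        promoter_window, downstream_window)
    }, integer(1))
    d <- abs(mids[i] - tss_all[idx])
    if (all(is.na(cats))) {
      pick <- idx[order(d, models$gene_id[idx])[1]]
      gene[i] <- models$gene_id[pick]
      dist[i] <- mids[i] - tss_all[pick]
      next
    }
    best <- min(cats, na.rm = TRUE)
    cand <- which(!is.na(cats) & cats == best)
    pick <- cand[order(d[cand], models$gene_id[idx][cand])[1]]
    category[i] <- FEATURE_LEVELS[best]
    gene[i] <- models$gene_id[idx][pick]
    dist[i] <- mids[i] - tss_all[idx][pick]
  }
  out <- peaks
  out$category <- factor(category, levels = FEATURE_LEVELS)
  out$gene_id <- gene
  out$distance_to_tss <- dist
  out
}

#' Aggregate annotated peak signal into promoter/other per gene
#'
#' Promoter-category signal sums into `promoter`; every other category
#' assigned to a gene sums into `other`. DistalIntergenic peaks are
#' credited to the nearest gene's `other` only within `max_distal` bp of
#' its TSS, and are dropped beyond that. Signal is each peak's `score`
#' (falling back to 1 when absent) times the sample's scale factor.
#'
#' @param annotated Output of [annotate_peaks()] with `sample_id`.
#' @param scale_factors Named per-sample factors (e.g. [spikein_factors()]);
#'   default all 1.
#' @param max_distal Maximum TSS distance for crediting distal signal.
#' @return Tibble: `gene_id`, `sample_id`, `promoter`, `other`.
#' @export
aggregate_region_signal <- function(annotated, scale_factors = NULL,
                                    max_distal = 1e5) {
  x <- annotated
  x$score <- ifelse(is.na(x$score), 1, x$score)
  if (is.null(scale_factors)) {
    scale_factors <- setNames(rep(1, length(unique(x$sample_id))), unique(x$sample_id))
  }
  x$signal <- x$score * scale_factors[x$sample_id]
  x <- x[!is.na(x$gene_id), ]
  drop <- x$category == "DistalIntergenic" & abs(x$distance_to_tss) > max_distal
  x <- x[!drop, ]
  x |>
    dplyr::mutate(region = ifelse(.data$category == "Promoter", "promoter", "other")) |>
    dplyr::group_by(.data$gene_id, .data$sample_id, .data$region) |>
    dplyr::summarise(signal = sum(.data$signal), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region", values_from = "signal",
                       values_fill = 0) |>
    (\(d) { for (col in c("promoter", "other")) if (!col %in% names(d)) d[[col]] <- 0; d })() |>
    dplyr::select("gene_id", "sample_id", "promoter", "other") |>
    dplyr::arrange(.data$gene_id, .data$sample_id)
}

#' Promoter fraction of total signal
#'
#' @param region_signal Tibble from [aggregate_region_signal()].
#' @return Tibble: `sample_id`, `promoter_fraction`.
#' @export
promoter_fraction <- function(region_signal) {
  out <- region_signal |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$promoter) + sum(.data$other),
                     promoter_fraction = sum(.data$promoter) / .data$total,
                     .groups = "drop")
  if (any(out$total <= 0)) {
    abort(sprintf("sample %s has zero total signal", out$sample_id[out$total <= 0][1]))
  }
  dplyr::select(out, "sample_id", "promoter_fraction")
}

#' Promoter-to-other shift typing
#'
#' From the gated sign of the promoter change (`dP`) and the other-region
#' change (`dO`) for one comparison: `Type1` is promoter-up/other-down,
#' `Type2` promoter-down/other-up, `None` both zero, `Type3` any other
#' combination. The Type1/Type2 direction convention is a label choice.
#'
#' @param dP,dO Integer trits in -1, 0, +1.
#' @return Character vector of shift types.
#' @export
shift_type <- function(dP, dO) {
  stopifnot(all(dP %in% c(-1L, 0L, 1L)), all(dO %in% c(-1L, 0L, 1L)))
  dplyr::case_when(
    dP == 1L & dO == -1L ~ "Type1",
    dP == -1L & dO == 1L ~ "Type2",
    dP == 0L & dO == 0L ~ "None",
    TRUE ~ "Type3"
  )
}

#' Run gated shift typing for one comparison
#'
#' Applies the gated differential engine separately to the promoter and
#' other-region count tables (same gate level, spike-in size factors when
#' provided) and types each gene from the two gated signs.
#'
#' @param promoter_counts,other_counts Count tibbles (genes x samples).
#' @param samples Sample sheet for those columns (needs `spike_in_reads`
#'   when `use_spikein`).
#' @param spec A [comparison_spec()].
#' @param alpha Gate level.
#' @param use_spikein Normalize by spike-in factors instead of
#'   median-of-ratios.
#' @param c0 Spike-in calibration constant.
#' @return Tibble: `gene_id`, `comparison`, `lobe`, `dP`, `dO`,
#'   `shift_type`, plus gated changes `g_promoter`, `g_other`.
#' @export
shift_typing <- function(promoter_counts, other_counts, samples, spec,
                         alpha = 0.05, use_spikein = TRUE, c0 = 10000) {
  sf <- NULL
  if (use_spikein) {
    if (!"spike_in_reads" %in% names(samples)) {
      abort("samples lacks spike_in_reads; set use_spikein = FALSE")
    }
    # size factors divide counts; the spike factor multiplies, so invert
    sf <- setNames(1 / spikein_factors(samples$spike_in_reads, c0), samples$sample_id)
  }
  rp <- run_comparison(promoter_counts, samples, spec, alpha = alpha, sf = sf)
  ro <- run_comparison(other_counts, samples, spec, alpha = alpha, sf = sf)
  merged <- dplyr::inner_join(
    dplyr::select(as_tibble(rp), "gene_id", g_promoter = "g"),
    dplyr::select(as_tibble(ro), "gene_id", g_other = "g"),
    by = "gene_id")
  merged |>
    dplyr::mutate(comparison = spec$label, lobe = spec$lobe,
                  dP = as.integer(sign(.data$g_promoter)),
                  dO = as.integer(sign(.data$g_other)),
                  shift_type = shift_type(.data$dP, .data$dO)) |>
    dplyr::select("gene_id", "comparison", "lobe", "dP", "dO", "shift_type",
                  "g_promoter", "g_other")
}
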