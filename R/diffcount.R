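#' Median-of-ratios size factors
#'
#' Library-size normalization in the DESeq style: each sample's factor is
#' the median, over reference genes, of its counts divided by the gene's
#' geometric mean across samples. Genes with a zero count in any sample are
#' excluded from the reference.
#'
#' @param counts Count tibble (`gene_id` first column).
#' @param pseudo_reference If no gene is nonzero in every sample, setting
#'   this to `TRUE` falls back to genes with positive geometric mean over
#'   the samples where they are nonzero.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 1) abort("no samples")
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) {
    if (!pseudo_reference) {
      abort(paste0("no gene has nonzero counts in all samples; ",
                   "rerun with pseudo_reference = TRUE"))
    }
    lg <- log(m)
    lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    ref <- is.finite(geo) & geo > 0
    if (!any(ref)) abort("all genes are entirely zero; cannot normalize")
  } else {
    geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  }
  ratios <- m[ref, , drop = FALSE] / geo
  sf <- apply(ratios, 2, median)
  if (any(!is.finite(sf) | sf <= 0)) abort("nonpositive size factor; data too sparse")
  setNames(sf, colnames(m))
}

#' Method-of-moments dispersion
#'
#' Per-gene negative binomial dispersion phi (variance = mu + phi mu^2)
#' estimated from normalized counts: residual variance after centering each
#' group at its own mean, pooled across groups, then
#' `phi = max(0, (s2 - mean) / mean^2)`, floored at `phi_min`.
#'
#' @param counts Count tibble.
#' @param sf Per-sample size factors (named as the sample columns).
#' @param groups Optional per-sample group labels; default one group.
#' @param phi_min Dispersion floor.
#' @return Named per-gene dispersion vector.
#' @export
estimate_dispersion <- function(counts, sf, groups = NULL, phi_min = 1e-8) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 2) abort("dispersion needs >= 2 samples")
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  if (is.null(groups)) groups <- rep("all", ncol(m))
  groups <- as.character(groups)
  resid <- norm
  for (g in unique(groups)) {
    idx <- groups == g
    resid[, idx] <- norm[, idx, drop = FALSE] - rowMeans(norm[, idx, drop = FALSE])
  }
  df <- ncol(m) - length(unique(groups))
  if (df < 1) abort("dispersion needs more samples than groups")
  s2 <- rowSums(resid^2) / df
  mbar <- rowMeans(norm)
  phi <- ifelse(mbar > 0, pmax(0, (s2 - mbar) / mbar^2), 0)
  structure(setNames(pmax(phi, phi_min), rownames(m)), df = df)
}

#' Label a pairwise comparison
#'
#' Builds the specification of one two-group contrast within a lobe. The
#' conventional labels concatenate the group letters with "v", numerator
#' first: `MvG` is treatment vs disease.
#'
#' @param numerator,denominator Group codes in `C`, `G`, `P`, `M`.
#' @param lobe Lobe code in `H`, `L`, `R1`, `R2`, `R3` (or `NA` when the
#'   design has no lobe structure).
#' @return A `comparison_spec` list.
#' @export
comparison_spec <- function(numerator, denominator, lobe = NA_character_) {
  if (!numerator %in% GROUPS || !denominator %in% GROUPS) {
    abort("groups must be one of C, G, P, M")
  }
  if (numerator == denominator) abort("numerator and denominator must differ")
  if (!is.na(lobe) && !lobe %in% LOBES) abort("unknown lobe")
  structure(list(numerator = numerator, denominator = denominator, lobe = lobe,
                 label = paste0(numerator, "v", denominator)),
            class = "comparison_spec")
}

#' Negative binomial Wald test
#'
#' For each gene, the log2 fold change of shrunken normalized group means
#' (pseudocount 0.5) is divided by a delta-method standard error built from
#' the NB variance `mu + phi mu^2`, and the statistic is referred to a t
#' distribution whose degrees of freedom match the dispersion estimate
#' (the `df` attribute set by [estimate_dispersion()], or n1 + n2 - 2 when
#' dispersions come from elsewhere); at large n this coincides with the
#' normal reference. Genes at zero in both groups get `log2fc = 0`,
#' `p = 1`.
#'
#' @param counts Count tibble restricted to the two groups' samples (extra
#'   samples are ignored via `groups`).
#' @param groups Per-sample labels; exactly the numerator and denominator
#'   values are used.
#' @param numerator,denominator Group labels to contrast (numerator on top).
#' @param sf Size factors; computed from `counts` when `NULL`.
#' @param phi Per-gene dispersions; estimated when `NULL`.
#' @param pseudocount Added to normalized group means before the log ratio.
#' @return Tibble: `gene_id`, `log2fc`, `se`, `p`.
#' @export
nb_wald_test <- function(counts, groups, numerator, denominator,
                         sf = NULL, phi = NULL, pseudocount = 0.5) {
  m <- counts_to_matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  i1 <- which(groups == denominator)
  i2 <- which(groups == numerator)
  if (length(i1) < 2 || length(i2) < 2) {
    abort(sprintf("need >= 2 replicates per side; got %d (%s) and %d (%s)",
                  length(i1), denominator, length(i2), numerator))
  }
  keep <- c(i1, i2)
  sub <- counts[, c(1L, 1L + keep)]
  gsub <- groups[keep]
  if (is.null(sf)) sf <- size_factors(sub, pseudo_reference = TRUE)
  if (is.null(phi)) phi <- estimate_dispersion(sub, sf, groups = gsub)
  ms <- counts_to_matrix(sub)
  norm <- sweep(ms, 2, sf[colnames(ms)], "/")
  n1 <- sum(gsub == denominator); n2 <- sum(gsub == numerator)
  m1 <- rowMeans(norm[, gsub == denominator, drop = FALSE])
  m2 <- rowMeans(norm[, gsub == numerator, drop = FALSE])
  log2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  v1 <- (m1 + phi * m1^2) / n1
  v2 <- (m2 + phi * m2^2) / n2
  se <- sqrt(v1 / (m1 + pseudocount)^2 + v2 / (m2 + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  t_df <- attr(phi, "df") %||% (n1 + n2 - 2)
  p <- 2 * pt(-abs(z), df = t_df)
  zero <- m1 == 0 & m2 == 0
  log2fc[zero] <- 0; p[zero] <- 1; se[zero] <- 0
  tibble(gene_id = rownames(ms), log2fc = unname(log2fc), se = unname(se),
         p = unname(pmin(p, 1)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; values are monotone in rank and capped at 1.
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Significance-gated signed change
#'
#' The gated change g keeps the log2 fold change only when the adjusted p
#' value clears `alpha`, and is zero otherwise; genes with a missing
#' adjusted p (untested) are gated to zero.
#'
#' @param log2fc Log2 fold changes.
#' @param padj Adjusted p values (may contain `NA`).
#' @param alpha Significance level for the gate.
#' @return Gated signed changes.
#' @export
gate <- function(log2fc, padj, alpha = 0.05) {
  if (any(!is.na(padj) & (padj < 0 | padj > 1))) abort("padj must lie in [0, 1]")
  ifelse(!is.na(padj) & padj <= alpha, log2fc, 0)
}

#' Run one gated pairwise comparison
#'
#' Composes normalization, dispersion estimation, the NB Wald test, BH
#' adjustment and the significance gate for one contrast within one lobe.
#'
#' @param counts Count tibble over all samples.
#' @param samples Sample sheet tibble.
#' @param spec A [comparison_spec()].
#' @param alpha Gate level.
#' @param sf Optional precomputed size factors over all of `counts`.
#' @param phi Optional precomputed per-gene dispersions (e.g. estimated once
#'   per lobe across all four groups, which stabilizes the estimate relative
#'   to the two-group default).
#' @return A `comparison_result` tibble: `gene_id`, `comparison`, `lobe`,
#'   `log2fc`, `se`, `p`, `padj`, `g`.
#' @export
run_comparison <- function(counts, samples, spec, alpha = 0.05, sf = NULL,
                           phi = NULL) {
  samples <- validate_sample_sheet(samples)
  sel <- samples$group %in% c(spec$numerator, spec$denominator) &
    (is.na(spec$lobe) | samples$lobe == spec$lobe)
  for (g in c(spec$denominator, spec$numerator)) {
    if (!any(samples$group[sel] == g)) {
      abort(sprintf("group %s absent for lobe %s", g, spec$lobe))
    }
  }
  sub_samples <- samples[sel, ]
  sub <- counts[, c("gene_id", sub_samples$sample_id)]
  res <- nb_wald_test(sub, sub_samples$group, spec$numerator, spec$denominator,
                      sf = sf[sub_samples$sample_id], phi = phi)
  res$padj <- bh_adjust(res$p)
  res$g <- gate(res$log2fc, res$padj, alpha)
  out <- dplyr::bind_cols(res[, "gene_id"],
                          tibble(comparison = spec$label, lobe = spec$lobe),
                          res[, c("log2fc", "se", "p", "padj", "g")])
  structure(out, class = c("comparison_result", class(out)),
            spec = spec, alpha = alpha)
}

#' Run all four standard comparisons for each lobe
#'
#' Size factors and per-gene dispersions are estimated once per lobe across
#' all four groups (group means centered), then shared by that lobe's four
#' contrasts — the extra residual degrees of freedom stabilize the
#' dispersion estimate relative to estimating it inside each two-group
#' contrast.
#'
#' @param counts Count tibble.
#' @param samples Sample sheet.
#' @param alpha Gate level.
#' @param lobes Lobes to process (default: those present).
#' @return One tibble of stacked comparison results.
#' @export
run_all_comparisons <- function(counts, samples, alpha = 0.05, lobes = NULL) {
  samples <- validate_sample_sheet(samples)
  lobes <- lobes %||% sort(unique(samples$lobe))
  pairs <- list(c("G", "C"), c("M", "G"), c("P", "G"), c("M", "P"))
  res <- purrr::map(lobes, function(lb) {
    lobe_samples <- samples[samples$lobe == lb, ]
    lobe_counts <- counts[, c("gene_id", lobe_samples$sample_id)]
    sf <- size_factors(lobe_counts, pseudo_reference = TRUE)
    phi <- estimate_dispersion(lobe_counts, sf, groups = lobe_samples$group)
    purrr::map(pairs, function(pr) {
      as_tibble(run_comparison(counts, samples, comparison_spec(pr[1], pr[2], lb),
                               alpha = alpha, sf = sf, phi = phi))
    }) |> list_rbind()
  }) |> list_rbind()
  res
}

#' @method tidy comparison_result
#' @export
tidy.comparison_result <- function(x, ...) as_tibble(x)

#' @method glance comparison_result
#' @export
glance.comparison_result <- function(x, ...) {
  tibble(comparison = attr(x, "spec")$label, lobe = attr(x, "spec")$lobe,
         alpha = attr(x, "alpha"), n_genes = nrow(x),
         n_significant = sum(x$g != 0),
         n_up = sum(x$g > 0), n_down = sum(x$g < 0))
}
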