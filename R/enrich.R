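#' Rank genes by gated change
#'
#' Builds the preranked list for GSEA: genes with nonzero gated change `g`,
#' ordered by `g` descending, ties broken lexicographically by `gene_id`.
#'
#' @param result Comparison-result tibble.
#' @return Tibble: `gene_id`, `score`, in rank order.
#' @export
rank_genes <- function(result) {
  nz <- result[result$g != 0, c("gene_id", "g")]
  if (nrow(nz) < 2) abort("need >= 2 genes with nonzero gated change to rank")
  if (anyDuplicated(nz$gene_id)) abort("duplicate gene_id in ranking input")
  nz <- nz[order(-nz$g, nz$gene_id), ]
  tibble(gene_id = nz$gene_id, score = nz$g)
}

#' Weighted running-sum enrichment score
#'
#' Classic preranked GSEA statistic: walking down the ranked list, a hit
#' adds `|score|^p` (normalized by the total over hits) and a miss
#' subtracts `1/(N - N_hits)`; the ES is the running sum's maximum
#' deviation from zero, signed.
#'
#' @param ranked Ranked tibble from [rank_genes()].
#' @param gene_set Character vector of member genes.
#' @param p Weight exponent.
#' @return ES in [-1, 1].
#' @export
gsea_es <- function(ranked, gene_set, p = 1) {
  hit <- ranked$gene_id %in% gene_set
  n <- nrow(ranked)
  n_hits <- sum(hit)
  if (n_hits == 0) abort("gene set does not intersect the ranked list")
  if (n_hits == n) abort("gene set covers the whole ranked list")
  w <- abs(ranked$score)^p
  steps <- ifelse(hit, w / sum(w[hit]), -1 / (n - n_hits))
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Normalized enrichment with a gene-set permutation null
#'
#' For each set, the null distribution of ES is built from `n_perm` random
#' same-size gene sets drawn from the ranked universe; `NES = ES /
#' mean(|null ES| of matching sign)`, the p value is the empirical
#' same-sign tail `(1 + #{|null| >= |ES|}) / (1 + #same-sign null)`, and p
#' values are BH-adjusted across sets. A set whose sign has no null mass is
#' flagged (`NES = NA`).
#'
#' @param ranked Ranked tibble.
#' @param sets Gene-set tibble (as from [read_gmt()]) or named list.
#' @param n_perm Number of permutations (>= 100).
#' @param p Weight exponent.
#' @param seed Seed for the permutation draw.
#' @return An `enrichment_result` tibble: `set_name`, `n_hits`, `es`,
#'   `nes`, `p`, `padj`.
#' @export
gsea_nes <- function(ranked, sets, n_perm = 1000, p = 1, seed = 1) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  if (is.data.frame(sets)) sets <- gene_set_list(sets)
  sets <- purrr::map(sets, intersect, y = ranked$gene_id)
  keep <- purrr::map_int(sets, length) > 0 &
    purrr::map_int(sets, length) < nrow(ranked)
  if (!all(keep)) {
    warn(sprintf("%d set(s) dropped (empty or full intersection with ranked list)",
                 sum(!keep)))
    sets <- sets[keep]
  }
  set.seed(derive_seed(seed, "gsea_perm"))
  sizes <- sort(unique(purrr::map_int(sets, length)))
  null_by_size <- lapply(sizes, function(k) {
    vapply(seq_len(n_perm), function(b) {
      gsea_es(ranked, sample(ranked$gene_id, k), p = p)
    }, numeric(1))
  })
  names(null_by_size) <- as.character(sizes)
  rows <- purrr::imap(sets, function(members, nm) {
    es <- gsea_es(ranked, members, p = p)
    null <- null_by_size[[as.character(length(members))]]
    same <- null[sign(null) == sign(es)]
    if (!length(same) || es == 0) {
      return(tibble(set_name = nm, n_hits = length(members), es = es,
                    nes = NA_real_, p = NA_real_))
    }
    tibble(set_name = nm, n_hits = length(members), es = es,
           nes = es / mean(abs(same)),
           p = (1 + sum(abs(same) >= abs(es))) / (1 + length(same)))
  })
  out <- list_rbind(rows)
  out$padj <- bh_adjust(out$p)
  structure(out, class = c("enrichment_result", class(out)),
            n_perm = n_perm, weight = p)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(x)

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_sets = nrow(x), n_perm = attr(x, "n_perm"),
         n_significant = sum(!is.na(x$padj) & x$padj <= 0.05))
}

#' Per-sample gene-set score (rank-walk statistic)
#'
#' Single-sample enrichment in the ssGSEA style: genes are ranked within
#' the sample (average ranks for ties, highest expression = largest rank);
#' walking down the list, the score accumulates the difference between the
#' rank-weighted in-set ECDF (weights `rank^alpha`) and the unweighted
#' out-of-set ECDF, then is normalized by the number of genes. Depending
#' only on ranks, it is invariant under strictly monotone transforms.
#'
#' @param expr Named expression vector for one sample/cell.
#' @param gene_set Member genes (must be a non-empty proper subset of the
#'   measured genes).
#' @param alpha Rank weight exponent.
#' @return Scalar score.
#' @export
sample_set_score <- function(expr, gene_set, alpha = 0.25) {
  in_set <- names(expr) %in% gene_set
  if (!any(in_set)) abort("gene set does not intersect the measured genes")
  if (all(in_set)) abort("gene set covers all measured genes")
  r <- rank(expr, ties.method = "average")
  ord <- order(-r, names(expr))
  in_ord <- in_set[ord]
  w <- r[ord]^alpha
  p_in <- cumsum(ifelse(in_ord, w, 0)) / sum(w[in_ord])
  p_out <- cumsum(!in_ord) / sum(!in_ord)
  sum(p_in - p_out) / length(expr)
}

#' Score many cells against many gene sets
#'
#' @param counts Gene x cell count tibble (`gene_id` first column).
#' @param sets Gene-set tibble or named list.
#' @param alpha Rank weight exponent.
#' @return Tibble: `cell_id`, one score column per set.
#' @export
score_cells <- function(counts, sets, alpha = 0.25) {
  if (is.data.frame(sets)) sets <- gene_set_list(sets)
  m <- counts_to_matrix(counts)
  scores <- purrr::map(sets, function(s) {
    apply(m, 2, function(col) {
      names(col) <- rownames(m)
      sample_set_score(col, s, alpha = alpha)
    })
  })
  dplyr::bind_cols(tibble(cell_id = colnames(m)), as_tibble(scores))
}

#' Flag poor-quality cells
#'
#' A cell is flagged when any metric violates its bound: features detected
#' outside [`min_features`, `max_features`], total counts outside
#' [`min_counts`, `max_counts`], mitochondrial percentage above `max_mito`,
#' or ribosomal percentage above `max_ribo`. Defaults are the standard
#' printed thresholds.
#'
#' @param cells Tibble with `nFeature`, `nCount`, `pct_mito`, `pct_ribo`.
#' @param min_features,max_features,min_counts,max_counts,max_mito,max_ribo
#'   Bounds.
#' @return `cells` plus logical `qc_flagged`.
#' @export
qc_filter <- function(cells, min_features = 400, max_features = 7000,
                      min_counts = 500, max_counts = 80000,
                      max_mito = 15, max_ribo = 40) {
  need <- c("nFeature", "nCount", "pct_mito", "pct_ribo")
  missing <- setdiff(need, names(cells))
  if (length(missing)) abort(paste0("missing QC metric(s): ", paste(missing, collapse = ", ")))
  dplyr::mutate(cells, qc_flagged =
    .data$nFeature < min_features | .data$nFeature > max_features |
    .data$nCount < min_counts | .data$nCount > max_counts |
    .data$pct_mito > max_mito | .data$pct_ribo > max_ribo)
}

#' Log-normalized expression
#'
#' `log1p(count / colsum * scale)`, the standard library-size
#' log-normalization for single-cell counts.
#'
#' @param counts Gene x cell count tibble.
#' @param scale Target library size.
#' @return Matrix (genes x cells).
#' @export
lognormalize <- function(counts, scale = 1e4) {
  m <- counts_to_matrix(counts)
  cs <- colSums(m)
  if (any(cs == 0)) abort("cell with zero total counts; filter first")
  log1p(sweep(m, 2, cs, "/") * scale)
}

#' Signature score per cell
#'
#' Mean of per-gene standardized log-normalized expression over the
#' signature genes (genes constant across cells contribute 0).
#'
#' @param counts Gene x cell count tibble.
#' @param signature_genes Character vector.
#' @return Named numeric vector of per-cell scores.
#' @export
signature_scores <- function(counts, signature_genes) {
  ln <- lognormalize(counts)
  sig <- intersect(rownames(ln), signature_genes)
  if (!length(sig)) abort("no signature gene is present in the matrix")
  sub <- ln[sig, , drop = FALSE]
  mu <- rowMeans(sub)
  sdev <- apply(sub, 1, sd)
  z <- (sub - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  colMeans(z)
}

#' Stratify cells into high/low by score
#'
#' High means strictly above the split quantile of the scores; ties at the
#' threshold go low.
#'
#' @param scores Numeric vector (>= 4 values, not all equal).
#' @param split_quantile Quantile for the threshold (default median).
#' @return Character vector `"high"`/`"low"`.
#' @export
stratify <- function(scores, split_quantile = 0.5) {
  if (length(scores) < 4) abort("need >= 4 cells to stratify")
  if (max(scores) == min(scores)) abort("scores are constant; no stratification possible")
  thr <- quantile(scores, split_quantile, names = FALSE)
  ifelse(scores > thr, "high", "low")
}

#' Rank-sum marker test with a detection filter
#'
#' Two-sided Wilcoxon rank-sum test per gene between two cell groups,
#' restricted to genes detected (count > 0) in at least `min_pct` of the
#' cells of at least one group; BH adjustment across tested genes. The
#' reported fold change is the log2 ratio of mean log-normalized expression
#' (pseudocount 0.5).
#'
#' @param counts Gene x cell count tibble.
#' @param groups Per-cell labels with exactly two levels.
#' @param min_pct Minimum detection fraction.
#' @return Tibble: `gene_id`, `pct_1`, `pct_2`, `log2fc`, `p`, `padj`.
#' @export
ranksum_markers <- function(counts, groups, min_pct = 0.3) {
  m <- counts_to_matrix(counts)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) abort("groups must have exactly two levels")
  i1 <- groups == lev[1]; i2 <- groups == lev[2]
  if (sum(i1) < 3 || sum(i2) < 3) abort("both groups need >= 3 cells")
  pct1 <- rowMeans(m[, i1, drop = FALSE] > 0)
  pct2 <- rowMeans(m[, i2, drop = FALSE] > 0)
  tested <- pct1 >= min_pct | pct2 >= min_pct
  if (!any(tested)) {
    inform("no genes pass the detection filter")
    return(tibble(gene_id = character(), pct_1 = double(), pct_2 = double(),
                  log2fc = double(), p = double(), padj = double()))
  }
  ln <- lognormalize(counts)
  rows <- purrr::map(which(tested), function(k) {
    x1 <- ln[k, i1]; x2 <- ln[k, i2]
    pv <- if (all(c(x1, x2) == c(x1, x2)[1])) 1 else
      suppressWarnings(wilcox.test(x2, x1)$p.value)
    tibble(gene_id = rownames(m)[k], pct_1 = pct1[k], pct_2 = pct2[k],
           log2fc = log2((mean(expm1(x2)) + 0.5) / (mean(expm1(x1)) + 0.5)),
           p = pv)
  })
  out <- list_rbind(rows)
  out$padj <- bh_adjust(out$p)
  out
}

#' Gated t-statistic matrix over strata
#'
#' Within each cell type, compares per-cell pathway scores between the high
#' and low strata with a Welch t test, BH-adjusts across pathways within
#' the cell type, and zeroes the t statistic wherever the adjusted p
#' exceeds `alpha`. Cell types with fewer than `min_cells` cells in either
#' stratum are flagged and not tested.
#'
#' @param scores Tibble from [score_cells()] (`cell_id` + one column per
#'   pathway).
#' @param strata Per-cell `"high"`/`"low"` labels aligned with `scores`.
#' @param cell_types Per-cell type labels aligned with `scores`.
#' @param alpha Gate level.
#' @param min_cells Minimum cells per stratum per cell type.
#' @return Tibble: `cell_type`, `pathway`, `n_high`, `n_low`, `t`, `p`,
#'   `padj`, `gated_t`, `flagged`.
#' @export
gated_t_matrix <- function(scores, strata, cell_types, alpha = 0.05,
                           min_cells = 3) {
  stopifnot(length(strata) == nrow(scores), length(cell_types) == nrow(scores))
  pathways <- setdiff(names(scores), "cell_id")
  rows <- purrr::map(sort(unique(cell_types)), function(ct) {
    sel <- cell_types == ct
    hi <- sel & strata == "high"; lo <- sel & strata == "low"
    per_path <- purrr::map(pathways, function(pw) {
      if (sum(hi) < min_cells || sum(lo) < min_cells) {
        return(tibble(cell_type = ct, pathway = pw, n_high = sum(hi),
                      n_low = sum(lo), t = NA_real_, p = NA_real_,
                      flagged = TRUE))
      }
      x_hi <- scores[[pw]][hi]; x_lo <- scores[[pw]][lo]
      if (sd(x_hi) == 0 && sd(x_lo) == 0) {
        tt <- list(statistic = c(t = 0), p.value = 1)
      } else {
        tt <- t.test(x_hi, x_lo)
      }
      tibble(cell_type = ct, pathway = pw, n_high = sum(hi), n_low = sum(lo),
             t = unname(tt$statistic), p = tt$p.value, flagged = FALSE)
    }) |> list_rbind()
    per_path$padj <- bh_adjust(per_path$p)
    per_path
  }) |> list_rbind()
  rows$gated_t <- ifelse(!rows$flagged & !is.na(rows$padj) & rows$padj <= alpha,
                         rows$t, 0)
  rows$gated_t[rows$flagged] <- NA_real_
  dplyr::select(rows, "cell_type", "pathway", "n_high", "n_low", "t", "p",
                "padj", "gated_t", "flagged")
}
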