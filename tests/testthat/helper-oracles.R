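# Independent oracles, written deliberately in a different style from the
# package code so they can catch shared mistakes.

# Benjamini-Hochberg by direct step-up evaluation
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) {
    for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  }
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force weighted running-sum enrichment score
gsea_es_oracle <- function(ids, scores, set, p = 1) {
  hits <- ids %in% set
  n_miss <- length(ids) - sum(hits)
  hit_total <- sum(abs(scores[hits])^p)
  run <- 0
  best <- 0
  for (i in seq_along(ids)) {
    run <- run + if (hits[i]) abs(scores[i])^p / hit_total else -1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  best
}

ORACLE_LEVELS <- c("Promoter", "FivePrimeUTR", "ThreePrimeUTR", "Exon",
                   "Intron", "Downstream", "DistalIntergenic")

# all-overlaps annotation oracle: for one midpoint, collect EVERY category
# that holds against EVERY gene, then resolve by precedence and nearest TSS
annotate_oracle_one <- function(mid, chrom, models, pw = 3000, dw = 3000) {
  rows <- list()
  for (k in seq_len(nrow(models))) {
    if (models$chrom[k] != chrom) next
    g_start <- models$start[k]; g_end <- models$end[k]
    strand <- models$strand[k]
    tss <- if (strand == "+") g_start else g_end - 1
    ex <- models$exons[[k]]
    cats <- character(0)
    if (mid >= tss - pw && mid <= tss + pw) cats <- c(cats, "Promoter")
    in_exon <- FALSE
    for (r in seq_len(nrow(ex))) {
      if (mid >= ex[r, 1] && mid < ex[r, 2]) in_exon <- TRUE
    }
    if (in_exon) {
      ts <- models$thick_start[k]; te <- models$thick_end[k]
      cds_exists <- ts < te
      if (cds_exists && strand == "+" && mid < ts) {
        cats <- c(cats, "FivePrimeUTR")
      } else if (cds_exists && strand == "+" && mid >= te) {
        cats <- c(cats, "ThreePrimeUTR")
      } else if (cds_exists && strand == "-" && mid >= te) {
        cats <- c(cats, "FivePrimeUTR")
      } else if (cds_exists && strand == "-" && mid < ts) {
        cats <- c(cats, "ThreePrimeUTR")
      } else {
        cats <- c(cats, "Exon")
      }
    } else if (mid >= g_start && mid < g_end) {
      cats <- c(cats, "Intron")
    }
    tes <- if (strand == "+") g_end - 1 else g_start
    if (strand == "+" && mid > tes && mid <= tes + dw) cats <- c(cats, "Downstream")
    if (strand == "-" && mid < tes && mid >= tes - dw) cats <- c(cats, "Downstream")
    if (length(cats)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = models$gene_id[k], dist = abs(mid - tss),
        lvl = min(match(cats, ORACLE_LEVELS)))
    }
  }
  on_chrom <- models[models$chrom == chrom, ]
  if (!length(rows)) {
    if (!nrow(on_chrom)) {
      return(list(category = "DistalIntergenic", gene_id = NA_character_))
    }
    tss_all <- ifelse(on_chrom$strand == "+", on_chrom$start, on_chrom$end - 1)
    d <- abs(mid - tss_all)
    pick <- order(d, on_chrom$gene_id)[1]
    return(list(category = "DistalIntergenic", gene_id = on_chrom$gene_id[pick]))
  }
  df <- do.call(rbind, rows)
  best <- min(df$lvl)
  df <- df[df$lvl == best, , drop = FALSE]
  df <- df[order(df$dist, df$gene_id), , drop = FALSE]
  list(category = ORACLE_LEVELS[best], gene_id = df$gene_id[1])
}

# exact two-sided rank-sum p by enumerating all group assignments
ranksum_p_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# random, possibly overlapping but individually valid gene models
random_models <- function(n_genes, chrom_len = 1e5, n_chroms = 1, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_genes), function(k) {
    chrom <- paste0("chr", sample(n_chroms, 1))
    start <- sample(0:(chrom_len - 5000), 1)
    end <- start + sample(2000:20000, 1)
    n_ex <- sample(1:3, 1)
    if (n_ex == 1) {
      exons <- cbind(start = start, end = end)
    } else {
      cuts <- sort(sample((start + 100):(end - 100), 2 * (n_ex - 1)))
      b <- c(start, cuts, end)
      exons <- cbind(start = b[seq(1, length(b), 2)], end = b[seq(2, length(b), 2)])
      exons <- exons[exons[, 1] < exons[, 2], , drop = FALSE]
    }
    thick <- sort(sample(start:end, 2))
    tibble::tibble(gene_id = sprintf("g%03d", k), chrom = chrom,
                   start = start, end = end,
                   strand = sample(c("+", "-"), 1),
                   thick_start = thick[1], thick_end = thick[2],
                   exons = list(exons))
  })
  dplyr::bind_rows(rows)
}

# odd-width random peaks (odd widths keep midpoints exact under mirroring)
random_peaks <- function(n, chrom_len = 1e5, n_chroms = 1, seed) {
  set.seed(seed)
  start <- sample(0:(chrom_len - 600), n, replace = TRUE)
  tibble::tibble(chrom = paste0("chr", sample(n_chroms, n, replace = TRUE)),
                 start = start, end = start + 2 * sample(50:250, n, replace = TRUE) + 1,
                 score = round(runif(n, 1, 100)), sample_id = "s1")
}

# mirror a genome of length L: reverse coordinates and strands
mirror_models <- function(models, L) {
  m <- models
  new_start <- L - models$end
  new_end <- L - models$start
  m$start <- new_start
  m$end <- new_end
  m$strand <- ifelse(models$strand == "+", "-", "+")
  m$thick_start <- L - models$thick_end
  m$thick_end <- L - models$thick_start
  m$exons <- lapply(models$exons, function(ex) {
    out <- cbind(start = L - ex[, 2], end = L - ex[, 1])
    out[order(out[, 1]), , drop = FALSE]
  })
  m
}

mirror_peaks <- function(peaks, L) {
  p <- peaks
  p$start <- L - peaks$end
  p$end <- L - peaks$start
  p
}

# two-group NB counts with per-gene planted log2 effects (numerator group 2)
nb_two_group <- function(n_genes, n_per_group, log2fc, mu = 1e4, phi = 0.05,
                         seed = 1, prefix = "G") {
  set.seed(seed)
  log2fc <- rep_len(log2fc, n_genes)
  mu_g <- mu * 2^runif(n_genes, -1, 1)
  ids <- sprintf("%s%04d", prefix, seq_len(n_genes))
  cols <- list()
  for (j in seq_len(n_per_group)) {
    cols[[paste0("A", j)]] <- rnbinom(n_genes, mu = mu_g, size = 1 / phi)
  }
  for (j in seq_len(n_per_group)) {
    cols[[paste0("B", j)]] <- rnbinom(n_genes, mu = mu_g * 2^log2fc, size = 1 / phi)
  }
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = ids), tibble::as_tibble(cols))
  samples <- tibble::tibble(
    sample_id = c(paste0("A", seq_len(n_per_group)), paste0("B", seq_len(n_per_group))),
    group = rep(c("G", "M"), each = n_per_group),
    lobe = "L", replicate = rep(seq_len(n_per_group), 2))
  list(counts = counts, samples = samples)
}
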