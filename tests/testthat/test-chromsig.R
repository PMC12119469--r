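test_that("spike-in factors are C/n and zero spike counts are an error", {
  expect_equal(unname(spikein_factors(10000)), 1)
  expect_equal(unname(spikein_factors(c(a = 5000, b = 20000))), c(2, 0.5))
  expect_error(spikein_factors(c(a = 5000, b = 0)), "b")
})

test_that("midpoint annotation resolves the precedence ladder on toy models", {
  # one + strand gene [10000, 20000) with terminal exons and a CDS inside
  gene <- tibble::tibble(
    gene_id = "toy", chrom = "chr1", start = 10000, end = 20000, strand = "+",
    thick_start = 10500, thick_end = 19500,
    exons = list(cbind(start = c(10000, 19000), end = c(11000, 20000))))

  probe <- function(s, e, models = gene) {
    annotate_peaks(tibble::tibble(chrom = "chr1", start = s, end = e,
                                  score = 1, sample_id = "s1"), models)
  }
  # midpoint exactly at the TSS
  at_tss <- probe(9900, 10100)
  expect_equal(as.character(at_tss$category), "Promoter")
  expect_equal(at_tss$distance_to_tss, 0)
  # intronic midpoint outside the promoter window
  expect_equal(as.character(probe(14000, 14200)$category), "Intron")
  # exonic midpoint past the CDS end
  expect_equal(as.character(probe(19600, 19700)$category), "ThreePrimeUTR")
  # exonic midpoint before the CDS start is promoter-shadowed; 5'UTR appears
  # once the promoter window shrinks
  expect_equal(as.character(annotate_peaks(
    tibble::tibble(chrom = "chr1", start = 10200, end = 10300, score = 1,
                   sample_id = "s1"), gene, promoter_window = 100)$category),
    "FivePrimeUTR")
  # just past the TES
  expect_equal(as.character(probe(21000, 21100)$category), "Downstream")
  # far away: distal with the nearest gene reported
  far <- probe(95000, 95100)
  expect_equal(as.character(far$category), "DistalIntergenic")
  expect_equal(far$gene_id, "toy")

  # a second gene whose promoter window covers the first gene's exon wins
  neighbor <- tibble::tibble(
    gene_id = "nbr", chrom = "chr1", start = 20500, end = 30000, strand = "+",
    thick_start = 20500, thick_end = 30000,
    exons = list(cbind(start = 20500, end = 30000)))
  both <- dplyr::bind_rows(gene, neighbor)
  in_exon_and_promoter <- probe(19400, 19500, both)
  expect_equal(as.character(in_exon_and_promoter$category), "Promoter")
  expect_equal(in_exon_and_promoter$gene_id, "nbr")

  # chromosome absent from the models
  expect_message(
    off <- annotate_peaks(tibble::tibble(chrom = "chrX", start = 1, end = 100,
                                         score = 1, sample_id = "s1"), gene),
    "absent")
  expect_equal(as.character(off$category), "DistalIntergenic")
  expect_true(is.na(off$gene_id))
})

test_that("every peak gets exactly one category and the oracle agrees on random genomes", {
  n_match <- 0
  for (trial in 1:30) {
    models <- random_models(sample(3:12, 1), seed = 100 + trial)
    peaks <- random_peaks(sample(10:40, 1), seed = 200 + trial)
    ann <- annotate_peaks(peaks, models)
    expect_equal(nrow(ann), nrow(peaks))
    expect_false(anyNA(ann$category))
    mids <- floor((peaks$start + peaks$end) / 2)
    for (i in seq_len(nrow(peaks))) {
      oracle <- annotate_oracle_one(mids[i], peaks$chrom[i], models)
      expect_equal(as.character(ann$category[i]), oracle$category,
                   label = sprintf("trial %d peak %d category", trial, i))
      expect_equal(ann$gene_id[i], oracle$gene_id,
                   label = sprintf("trial %d peak %d gene", trial, i))
      n_match <- n_match + 1
    }
  }
  expect_gt(n_match, 200)
})

test_that("annotation is invariant under genome mirroring", {
  L <- 1e5
  for (trial in 1:10) {
    models <- random_models(6, chrom_len = L, seed = 300 + trial)
    peaks <- random_peaks(25, chrom_len = L - 600, seed = 400 + trial)
    fwd <- annotate_peaks(peaks, models)
    rev <- annotate_peaks(mirror_peaks(peaks, L), mirror_models(models, L))
    expect_equal(as.character(rev$category), as.character(fwd$category))
    expect_equal(rev$gene_id, fwd$gene_id)
  }
})

test_that("region aggregation matches hand tallies and honors scale factors", {
  gene <- tibble::tibble(
    gene_id = "toy", chrom = "chr1", start = 10000, end = 20000, strand = "+",
    thick_start = 10000, thick_end = 20000,
    exons = list(cbind(start = 10000, end = 20000)))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(9950, 14000, 16000), end = c(10050, 14100, 16100),
    score = c(5, 3, 2), sample_id = "s1")
  ann <- annotate_peaks(peaks, gene)
  rs <- aggregate_region_signal(ann, c(s1 = 1))
  expect_equal(rs$promoter, 5)
  expect_equal(rs$other, 3 + 2)

  rs2 <- aggregate_region_signal(ann, c(s1 = 2))
  expect_equal(rs2$promoter, 10)
  expect_equal(rs2$other, 10)

  # all peaks in the promoter: other is zero
  prom_only <- annotate_peaks(peaks[1, ], gene)
  rs3 <- aggregate_region_signal(prom_only, c(s1 = 1))
  expect_equal(rs3$other, 0)

  # distal signal beyond max_distal is dropped
  far <- annotate_peaks(tibble::tibble(chrom = "chr1", start = 90000,
                                       end = 90100, score = 9,
                                       sample_id = "s1"), gene)
  expect_equal(nrow(aggregate_region_signal(far, c(s1 = 1), max_distal = 1e4)), 0)
  near <- aggregate_region_signal(far, c(s1 = 1), max_distal = 1e5)
  expect_equal(near$other, 9)
})

test_that("promoter fraction is bounded and fails on zero totals", {
  rs <- tibble::tibble(gene_id = c("a", "b"), sample_id = "s1",
                       promoter = c(3, 1), other = c(0, 0))
  expect_equal(promoter_fraction(rs)$promoter_fraction, 1)
  rs$promoter <- c(0, 0); rs$other <- c(2, 2)
  expect_equal(promoter_fraction(rs)$promoter_fraction, 0)
  rs$other <- c(0, 0)
  expect_error(promoter_fraction(rs), "zero total")
})

test_that("shift typing partitions the nine sign cells exactly", {
  grid <- expand.grid(dP = c(-1L, 0L, 1L), dO = c(-1L, 0L, 1L))
  types <- shift_type(grid$dP, grid$dO)
  expect_equal(sum(types == "Type1"), 1)
  expect_equal(sum(types == "Type2"), 1)
  expect_equal(sum(types == "None"), 1)
  expect_equal(sum(types == "Type3"), 6)
  expect_equal(types[grid$dP == 1 & grid$dO == -1], "Type1")
  expect_equal(types[grid$dP == -1 & grid$dO == 1], "Type2")
  expect_equal(types[grid$dP == 0 & grid$dO == 0], "None")
  expect_equal(types[grid$dP == 1 & grid$dO == 1], "Type3")
  expect_equal(types[grid$dP == 0 & grid$dO == -1], "Type3")
})

test_that("gated shift typing recovers planted types through spike calibration", {
  m <- sim_gene_models(n_genes = 100, seed = 41)
  ch <- sim_chromatin(m, n_samples_per_group = 3, seed = 41)
  st <- shift_typing(ch$promoter_counts, ch$other_counts, ch$samples,
                     comparison_spec("M", "G", "L"))
  truth <- ch$truth$shift_type[match(st$gene_id, ch$truth$gene_id)]
  planted <- truth %in% c("Type1", "Type2")
  expect_gte(mean(st$shift_type[planted] == truth[planted]), 0.7)
  # gating law holds on the underlying gated changes
  expect_true(all((st$dP == 0) == (st$g_promoter == 0)))
  expect_error(shift_typing(ch$promoter_counts, ch$other_counts,
                            dplyr::select(ch$samples, -spike_in_reads),
                            comparison_spec("M", "G", "L")),
               "spike_in_reads")
})
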