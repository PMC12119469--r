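test_that("simulators are byte-deterministic for a fixed seed", {
  expect_identical(sim_bulk(n_genes = 40, lobes = "L", seed = 5),
                   sim_bulk(n_genes = 40, lobes = "L", seed = 5))
  m <- sim_gene_models(n_genes = 10, seed = 5)
  expect_identical(sim_chromatin(m, seed = 5), sim_chromatin(m, seed = 5))
  expect_identical(sim_sc(n_cells = 50, n_background = 20, seed = 5),
                   sim_sc(n_cells = 50, n_background = 20, seed = 5))
})

test_that("planted NE genes are null and Rein02 genes carry the planted fold change", {
  # NE genes: per-group means indistinguishable (oracle t-test, Bonferroni)
  b <- sim_bulk(n_genes = 40, n_reps_per_cell = 50, lobes = "L", seed = 6,
                label_proportions = c(NE = 1, Rein01 = 0, Rein02 = 0,
                                      SR = 0, Whip01 = 0))
  sf <- size_factors(b$counts)
  norm <- sweep(as.matrix(b$counts[, -1]), 2, sf, "/")
  grp <- b$samples$group
  pvals <- apply(norm, 1, function(x) t.test(x[grp == "G"], x[grp == "C"])$p.value)
  expect_true(all(p.adjust(pvals, "bonferroni") > 0.05))

  # Rein02 genes at effect 2: G/C normalized mean ratio near 4-fold.
  # Planted genes are kept a minority so median-of-ratios normalization
  # (which assumes most genes unchanged) stays valid.
  b2 <- sim_bulk(n_genes = 100, n_reps_per_cell = 300, lobes = "L", seed = 7,
                 effect_log2fc = 2,
                 label_proportions = c(NE = 0.8, Rein01 = 0, Rein02 = 0.2,
                                       SR = 0, Whip01 = 0))
  sf2 <- size_factors(b2$counts)
  norm2 <- sweep(as.matrix(b2$counts[, -1]), 2, sf2, "/")
  grp2 <- b2$samples$group
  ratio <- rowMeans(norm2[, grp2 == "G"]) / rowMeans(norm2[, grp2 == "C"])
  r2 <- b2$truth$label == "Rein02"
  oriented <- ratio[r2]^b2$truth$sign[r2]
  expect_true(all(oriented >= 3.4 & oriented <= 4.7))
})

test_that("simulated counts are overdispersed in aggregate", {
  b <- sim_bulk(n_genes = 200, n_reps_per_cell = 5, lobes = "L", seed = 8,
                label_proportions = c(NE = 1, Rein01 = 0, Rein02 = 0,
                                      SR = 0, Whip01 = 0))
  sf <- size_factors(b$counts)
  norm <- sweep(as.matrix(b$counts[, -1]), 2, sf, "/")
  v <- apply(norm, 1, var)
  m <- rowMeans(norm)
  expect_gt(mean(v > m), 0.95)
})

test_that("gene model packing respects gaps, spans and promoter disjointness", {
  m <- sim_gene_models(n_genes = 10, chrom_sizes = c(chr1 = 1e6), seed = 9)
  expect_equal(nrow(m), 10)
  expect_true(all(m$start < m$end))
  # non-overlapping along the chromosome
  ord <- m[order(m$start), ]
  expect_true(all(head(ord$end, -1) <= tail(ord$start, -1)))
  # promoter windows pairwise disjoint (exhaustive)
  tss <- ifelse(m$strand == "+", m$start, m$end - 1)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_gt(abs(tss[i] - tss[j]), 6000)
  }
  expect_error(sim_gene_models(n_genes = 10, chrom_sizes = c(chr1 = 2e4), seed = 9),
               "cannot pack")
})

test_that("chromatin simulation realizes the promoter fraction and planted shifts", {
  m <- sim_gene_models(n_genes = 80, seed = 10)
  ch <- sim_chromatin(m, n_samples_per_group = 3, seed = 10)
  pc <- as.matrix(ch$promoter_counts[, -1])
  oc <- as.matrix(ch$other_counts[, -1])
  frac <- colSums(pc) / (colSums(pc) + colSums(oc))
  expect_true(all(frac >= 0.55 & frac <= 0.65))

  # Type1: promoter mean up, other mean down between the contrasted groups
  grp <- ch$samples$group
  lib <- 10000 / ch$samples$spike_in_reads
  pcal <- sweep(pc, 2, lib, "*")
  ocal <- sweep(oc, 2, lib, "*")
  t1 <- ch$truth$shift_type == "Type1"
  pr <- rowMeans(pcal[t1, grp == "M", drop = FALSE]) /
    rowMeans(pcal[t1, grp == "G", drop = FALSE])
  orat <- rowMeans(ocal[t1, grp == "M", drop = FALSE]) /
    rowMeans(ocal[t1, grp == "G", drop = FALSE])
  expect_true(all(pr > 1))
  expect_true(all(orat < 1))

  expect_error(sim_chromatin(m, spike_mean = 0), "spike_mean")

  # fixed seed: identical BED bytes
  d <- withr::local_tempdir()
  write_bed_peaks(ch$peaks[ch$peaks$sample_id == ch$samples$sample_id[1], ],
                  file.path(d, "a.bed"))
  ch2 <- sim_chromatin(m, n_samples_per_group = 3, seed = 10)
  write_bed_peaks(ch2$peaks[ch2$peaks$sample_id == ch2$samples$sample_id[1], ],
                  file.path(d, "b.bed"))
  expect_identical(readLines(file.path(d, "a.bed")),
                   readLines(file.path(d, "b.bed")))
})

test_that("single-cell generator plants exactly the requested QC outliers", {
  sc <- sim_sc(n_cells = 1000, qc_outlier_fraction = 0.1, n_background = 30,
               seed = 11)
  flagged <- qc_filter(sc$cells)$qc_flagged
  expect_equal(sum(flagged), 100)
  expect_equal(flagged, sc$truth$qc_outlier)
  expect_error(sim_sc(n_cells = 10, qc_outlier_fraction = 0.6), "0.5")
  expect_error(sim_sc(n_cells = 10, type_proportions = c(weird = 1)),
               "unknown cell type")
  expect_error(sim_sc(n_cells = 10, signature_genes = character()), "non-empty")
})

test_that("marker genes are elevated only in their own cell type", {
  sc <- sim_sc(n_cells = 600, n_background = 30, seed = 12,
               signature_effect_log2fc = 0)
  ln <- lognormalize(sc$counts)
  type <- sc$truth$cell_type
  for (ct in c("T", "myeloid")) {
    markers <- lobeomics:::sc_marker_sets()[[ct]]
    own <- rowMeans(ln[markers, type == ct, drop = FALSE])
    other <- rowMeans(ln[markers, type != ct, drop = FALSE])
    expect_true(all(own > other + 1))
  }
})

test_that("fixture bundles are reproducible, refuse overwrites and stay small", {
  d1 <- file.path(withr::local_tempdir(), "b1")
  d2 <- file.path(withr::local_tempdir(), "b2")
  m1 <- write_fixture_bundle(d1, "tiny", seed = 3)
  write_fixture_bundle(d2, "tiny", seed = 3)
  expect_equal(m1$seed, 3)

  files <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  expect_error(write_fixture_bundle(d1, "tiny", seed = 3), "force")
  expect_lt(sum(file.size(list.files(d1, recursive = TRUE, full.names = TRUE))),
            5e6)
})
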