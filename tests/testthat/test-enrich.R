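test_that("gene ranking orders by gated change with lexicographic ties", {
  res <- tibble::tibble(gene_id = c("c", "a", "b", "d"),
                        g = c(0, 2, -1, 2))
  r <- rank_genes(res)
  expect_equal(r$gene_id, c("a", "d", "b"))
  expect_equal(r$score, c(2, 2, -1))
  expect_error(rank_genes(tibble::tibble(gene_id = "a", g = 1)), ">= 2")
})

test_that("enrichment score hits the extreme cases and matches the brute-force oracle", {
  ranked <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                           score = c(2, 2, -2, -2))
  expect_equal(gsea_es(ranked, "a"), 1)
  expect_equal(gsea_es(ranked, "d"), -1)
  expect_error(gsea_es(ranked, "zz"), "does not intersect")
  expect_error(gsea_es(ranked, ranked$gene_id), "whole ranked list")

  set.seed(61)
  for (trial in 1:100) {
    n <- sample(3:20, 1)
    ids <- sprintf("g%02d", sample(99, n))
    scores <- sort(round(rnorm(n), 3), decreasing = TRUE)
    set <- sample(ids, sample(seq_len(n - 1), 1))
    rt <- tibble::tibble(gene_id = ids, score = scores)
    expect_equal(gsea_es(rt, set), gsea_es_oracle(ids, scores, set),
                 label = sprintf("trial %d", trial))
  }
})

test_that("NES has the sign of ES, calibrated magnitude, and detects planted sets", {
  set.seed(62)
  ids <- sprintf("g%03d", 1:100)
  ranked <- tibble::tibble(gene_id = ids,
                           score = sort(rnorm(100), decreasing = TRUE))
  sets <- lapply(1:30, function(k) sample(ids, 10))
  names(sets) <- sprintf("S%02d", 1:30)
  nes <- gsea_nes(ranked, sets, n_perm = 300, seed = 1)
  expect_true(all(sign(nes$nes) == sign(nes$es), na.rm = TRUE))
  expect_true(all(nes$p >= 1 / 301 & nes$p <= 1, na.rm = TRUE))
  expect_true(all(nes$padj >= nes$p, na.rm = TRUE))
  expect_gte(mean(abs(nes$nes), na.rm = TRUE), 0.8)
  expect_lte(mean(abs(nes$nes), na.rm = TRUE), 1.2)

  # planted top-loaded set
  planted <- list(TOP = ids[1:10], RAND = sample(ids, 10))
  out <- gsea_nes(ranked, planted, n_perm = 300, seed = 2)
  expect_gt(out$nes[out$set_name == "TOP"], 0)
  expect_lte(out$padj[out$set_name == "TOP"], 0.05)

  # fixed seed reproduces the table
  expect_identical(tibble::as_tibble(gsea_nes(ranked, sets, n_perm = 200, seed = 9)),
                   tibble::as_tibble(gsea_nes(ranked, sets, n_perm = 200, seed = 9)))
})

test_that("per-sample rank-walk score is rank-based and maximal for top placement", {
  set.seed(63)
  expr <- setNames(rexp(30), sprintf("g%02d", 1:30))
  s <- sample(names(expr), 5)
  expect_equal(sample_set_score(expr, s), sample_set_score(expr^3, s))
  expect_equal(sample_set_score(expr, s), sample_set_score(log(expr + 1), s))

  # exhaustive placement check: N = 8, |S| = 2; the top-2 placement maximizes
  vals <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), letters[1:8])
  placements <- utils::combn(names(vals), 2, simplify = FALSE)
  scores <- vapply(placements, function(s) sample_set_score(vals, s), numeric(1))
  top <- which(vapply(placements, function(s) setequal(s, c("a", "b")), logical(1)))
  expect_equal(which.max(scores), top)

  # identical rank order, different magnitudes: identical scores
  a <- setNames(c(5, 4, 3, 2, 1), letters[1:5])
  b <- setNames(c(100, 9, 8, 0.5, 0.1), letters[1:5])
  expect_equal(sample_set_score(a, c("a", "c")), sample_set_score(b, c("a", "c")))
})

test_that("QC filtering applies each printed bound", {
  cells <- tibble::tibble(
    cell_id = sprintf("c%d", 1:6),
    nFeature = c(300, 1000, 8000, 1000, 1000, 1000),
    nCount = c(5000, 400, 5000, 5000, 5000, 5000),
    pct_mito = c(5, 5, 5, 16, 5, 5),
    pct_ribo = c(10, 10, 10, 10, 45, 10))
  out <- qc_filter(cells)
  expect_equal(out$qc_flagged, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(qc_filter(dplyr::select(cells, -pct_ribo)), "pct_ribo")
})

test_that("stratification splits at the quantile with ties going low", {
  expect_equal(stratify(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(stratify(c(1, 2, 2, 3)), c("low", "low", "low", "high"))
  expect_error(stratify(c(1, 1, 1, 1)), "constant")
  expect_error(stratify(c(1, 2)), ">= 4")
})

test_that("rank-sum markers respect min.pct and match exact enumeration", {
  # gene detected in 10% of both groups is excluded
  set.seed(64)
  m <- matrix(rpois(20 * 100, 5), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%03d", 1:100)))
  m[1, ] <- 0
  m[1, sample(100, 10)] <- 1
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                             tibble::as_tibble(m))
  groups <- rep(c("high", "low"), 50)
  res <- ranksum_markers(counts, groups, min_pct = 0.3)
  expect_false("g01" %in% res$gene_id)
  expect_true("g02" %in% res$gene_id)

  # identical multisets across groups give p = 1
  tiny <- dplyr::bind_cols(
    tibble::tibble(gene_id = "g1"),
    tibble::as_tibble(setNames(as.list(c(3, 1, 2, 3, 1, 2)), sprintf("c%d", 1:6))))
  res_tiny <- ranksum_markers(tiny, rep(c("a", "b"), each = 3), min_pct = 0)
  expect_equal(res_tiny$p, 1)

  # n <= 5 per group, tie-free: p equals exhaustive permutation enumeration
  set.seed(65)
  for (trial in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    vals <- sample(seq(10, 200, by = 7), n1 + n2)
    cnt <- dplyr::bind_cols(
      tibble::tibble(gene_id = "g1"),
      tibble::as_tibble(setNames(as.list(vals), sprintf("c%d", seq_along(vals)))))
    grp <- c(rep("a", n1), rep("b", n2))
    got <- ranksum_markers(cnt, grp, min_pct = 0)$p
    # oracle on the log-normalized values the test actually ranks
    ln <- lognormalize(cnt)[1, ]
    expect_equal(got, ranksum_p_oracle(ln[grp == "b"], ln[grp == "a"]),
                 tolerance = 1e-12, label = sprintf("trial %d", trial))
  }
})

test_that("gated t matrix zeroes non-significant rows and flags tiny strata", {
  set.seed(66)
  n <- 60
  scores <- tibble::tibble(cell_id = sprintf("c%02d", 1:n),
                           up_path = c(rnorm(n / 2, 2), rnorm(n / 2, 0)),
                           null_path = rnorm(n))
  strata <- rep(c("high", "low"), each = n / 2)
  types <- rep("T", n)
  gt <- gated_t_matrix(scores, strata, types)
  expect_gt(gt$gated_t[gt$pathway == "up_path"], 0)
  expect_equal(gt$gated_t[gt$pathway == "null_path"], 0)

  # identical strata: t = 0, gated 0
  same <- tibble::tibble(cell_id = sprintf("c%d", 1:8), pw = rep(c(1, 2), 4))
  gt2 <- gated_t_matrix(same, rep(c("high", "low"), 4), rep("T", 8))
  expect_equal(gt2$t, 0)
  expect_equal(gt2$gated_t, 0)

  # a stratum below min_cells is flagged, not computed
  gt3 <- gated_t_matrix(scores[1:4, ], c("high", "low", "low", "low"),
                        rep("T", 4))
  expect_true(all(gt3$flagged))
  expect_true(all(is.na(gt3$gated_t)))
})
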