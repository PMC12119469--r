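# lobeomics

Integrated analysis of four-arm treatment studies — control (C), disease
(G), vehicle (P) and treatment (M) — measured across anatomical units
(lung lobes H, L, R1, R2, R3), with paired bulk transcriptomes and H3K27ac
chromatin signal plus a single-cell arm. The motivating setting is acute
graft-versus-host disease of the lung treated with mesenchymal stem cells,
where the question is which genes the treatment actually *reverses*, in
which lobes, and whether transcription and promoter chromatin move
together. The package is for computational biologists who want that
analysis as a reusable, tested pipeline rather than a one-off script
stack.

## The statistics at its core

Everything is built on the **gated signed change** for numerator group *j*
vs denominator *i*:

```
g_ij = log2FC_ij   if p.adj <= 0.05
g_ij = 0           otherwise
```

computed by an internal negative binomial Wald test (median-of-ratios or
spike-in normalization, per-gene method-of-moments dispersion, t reference
with df matched to the dispersion estimate, Benjamini–Hochberg within each
comparison and lobe). On top of the gated signs:

* **Trend taxonomy** — each gene's sign pattern over (GvC, MvG, PvG, MvP)
  is classified by an ordered, configurable rule table into `NE`,
  `Rein01`, `Rein02` (treatment reverses the disease trend; the candidate
  therapeutic mediators), `SR` (self-recovery) and `Whip01`
  (exacerbation), with shared and lobe-specific sets over the five lobes.
* **Promoter-shift typing** — H3K27ac peaks are annotated by midpoint with
  promoter precedence (±3 kb of the TSS), promoter vs other-region signal
  is tested separately after spike-in calibration, and each gene gets
  `Type1` (promoter up / other down), `Type2` (mirror), `Type3` or `None`.
* **Concordance (a-DEGs)** — genes significant in the same direction in
  both RNA and promoter chromatin for a comparison, intersected with the
  trend sets.
* **Enrichment** — preranked GSEA on the gated changes with a gene-set
  permutation NES, and a deterministic per-cell rank-walk score (ssGSEA
  family).
* **Single-cell stratification** — QC at the standard printed bounds,
  signature-score median split, and a Welch-t matrix per cell type with t
  values zeroed wherever adjusted p > 0.05.

A seeded synthetic-data generator (`sim_bulk`, `sim_chromatin`, `sim_sc`,
`write_fixture_bundle`) plants known trend labels, shift types and strata
so every stage is testable end to end without any download.

## Worked example

```r
library(lobeomics)

b <- sim_bulk(n_genes = 500, n_reps_per_cell = 3, lobes = "L", seed = 20)
res <- run_comparison(b$counts, b$samples, comparison_spec("M", "G", "L"))
glance(res)
#> # A tibble: 1 × 7
#>   comparison lobe  alpha n_genes n_significant  n_up n_down
#>   <chr>      <chr> <dbl>   <int>         <int> <int>  <int>
#> 1 MvG        L      0.05     500           122    60     62
```

122 of 500 genes pass the gate for treatment vs disease in the L lobe;
their `g` column carries the signed log2 fold change, everything else is
exactly zero. Classifying the full four-comparison pattern:

```r
rna <- run_all_comparisons(b$counts, b$samples)
trends <- assign_trends(rna)
dplyr::count(trends, label)
#> # A tibble: 5 × 2
#>   label      n
#>   <chr>  <int>
#> 1 NE       314
#> 2 Rein01    45
#> 3 Rein02    49
#> 4 SR        47
#> 5 Whip01    45
```

The generator planted 300 NE genes and 50 of each effect class at
|log2FC| = 2.5; the confusion matrix against `b$truth` is near-diagonal
(47/50 planted Rein02 recovered, 2 false Rein02 calls). `autoplot(res)`
gives the volcano, `plot_trend_counts(trends)` the per-lobe label counts,
and `write_fixture_bundle()` + `run_pipeline(pipeline_config(...))` run
the whole pipeline (differential, trends, chromatin, a-DEGs, enrichment,
single cell) to deterministic TSVs with a manifest.

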