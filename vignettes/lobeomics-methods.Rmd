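---
title: "Methods: gated differential changes, trend taxonomy and promoter-shift typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gated differential changes, trend taxonomy and promoter-shift typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobeomics)
```

`lobeomics` analyses four-arm treatment studies — control (C), disease (G),
vehicle (P) and treatment (M) — measured per anatomical unit (the five lung
lobes H, L, R1, R2, R3), with paired bulk transcriptomes and H3K27ac
chromatin signal, plus a single-cell arm. This vignette is the package's
account of the statistics it implements, the defaults it chose where the
design was genuinely open, and what its synthetic-data tests do and do not
establish about real data.

## The gated signed change

Every downstream stage consumes one primitive: for a pairwise comparison
of numerator group $j$ against denominator group $i$, each gene's *gated
signed change* is

$$
g_{ij} \;=\; \begin{cases}
\log_2\!\mathrm{FC}_{ij} & \text{if } p_{\mathrm{adj}} \le 0.05\\[2pt]
0 & \text{otherwise.}
\end{cases}
$$

Setting non-significant changes to exactly zero makes the sign of $g$ a
three-valued code (−1, 0, +1) that the trend taxonomy, the shift typing and
the concordance stage can all consume without re-deciding significance.
The gate level $\alpha = 0.05$ is a parameter everywhere but is the
intended operating point.

### The differential engine

The engine is intentionally self-contained and pluggable — the classifier
only ever sees `(log2fc, padj)`, so any engine producing those two columns
can be substituted. The internal default:

* **Normalization.** Median-of-ratios size factors over genes with no zero
  counts; a pseudo-reference fallback (geometric mean over nonzero entries)
  is available for sparse tables. Chromatin counts can instead be
  calibrated by spike-in factors $C/n_{\text{spike}}$ with $C = 10^4$;
  `shift_typing()` uses these by default, so a sample sequenced twice as
  deep contributes the same calibrated signal.
* **Dispersion.** Per-gene method of moments on normalized counts:
  group means are centered out, the pooled residual variance $s^2$ gives
  $\hat\varphi = \max\{0, (s^2 - \bar\mu)/\bar\mu^2\}$, floored at
  $10^{-8}$. There is deliberately no shrinkage across genes; the estimator
  is transparent and its residual degrees of freedom are known exactly.
* **Test.** The log2 fold change of normalized group means (pseudocount
  0.5) is divided by a delta-method standard error from the NB variance
  $\mu + \varphi\mu^2$. The statistic is referred to a **t distribution
  whose degrees of freedom equal the dispersion estimator's residual df**,
  not to a normal. At $n = 3$ vs 3 a normal reference is visibly
  anti-conservative (about 10% raw $p < 0.05$ under the null in our
  simulations, versus 4–5% for the matched-df t), and the df matters in
  the other direction too: when dispersion is pooled per lobe (df 8, see
  below), referring to $t_4$ throws away real power. At large $n$ the two
  references coincide.
* **Pooling.** `run_all_comparisons()` estimates size factors and
  dispersion once per lobe across all four groups (12 samples, df 8 at
  $n=3$) and shares them over the lobe's four contrasts (GvC, MvG, PvG,
  MvP). This is the standard design-wide dispersion practice and roughly
  halves the estimator's noise relative to per-contrast estimation.
  `run_comparison()` called directly still estimates from its own two
  groups.
* **Multiple testing.** Benjamini–Hochberg per comparison per lobe across
  all tested genes. Genes at zero in both groups are reported with
  $g = 0$, $p = 1$ rather than dropped, so set algebra over lobes has a
  common gene universe.
* **Conventions.** Swapping numerator and denominator negates `log2fc`
  and `g` and leaves `p` unchanged; scaling one sample's counts and its
  size factor by the same constant changes nothing. Both are enforced by
  tests.

## The five-type trend taxonomy

For each gene and lobe, the sign pattern
$(s_{GvC}, s_{MvG}, s_{PvG}, s_{MvP})$ of the four gated changes is matched
against an ordered rule table; the first matching row wins and a trailing
wildcard row supplies the fallback, so all $3^4 = 81$ patterns are covered
(enforced at load time). The default table encodes:

| label | meaning | pattern (first match wins) |
|---|---|---|
| `Rein02` | treatment reverses the disease trend and the vehicle does not; includes disease-silent genes whose vehicle trend the treatment reverses | $s_2 = -s_1 \ne 0,\ s_3 \ne -s_1$; or $s_1 = 0,\ s_2 = -s_3 \ne 0$ |
| `Rein01` | treatment *and* vehicle reverse the disease trend | $s_2 = s_3 = -s_1 \ne 0$ |
| `SR` | self-recovery: vehicle reverses, treatment silent | $s_3 = -s_1 \ne 0,\ s_2 = 0$ |
| `Whip01` | treatment moves with the disease trend | $s_2 = s_1 \ne 0$ |
| `NE` | everything else, including all-zero | fallback |

Two deliberate openings. First, the exact branch structure distinguishing
`Rein01` from `Rein02` (is the vehicle-also-reversed case a separate class
or a subset?) is not fully pinned down by the source material's prose, so
the table is *configuration*: it serializes to a TSV with trit wildcards
and any alternative reading is a config edit, never an engine change.
Second, $s_{MvP}$ is computed and stored but unused by the default rules;
custom tables may use it. Every rule in the default table is
sign-symmetric, so negating all four trits never changes the label — an
exhaustively enumerated test.

Per-lobe label sets feed `shared_specific()`: the shared set (present in
all five lobes), lobe-specific sets (present in exactly one), and the full
UpSet-style count over all $2^5 - 1$ membership classes, whose total is
checked against the union size.

## Chromatin: annotation, promoter fraction, shift typing

Peaks are assigned by their **midpoint** to exactly one feature category
with fixed precedence

Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream > DistalIntergenic,

where the promoter window is ±3 kb around the strand-aware TSS (the same
flank the field's TSS heatmaps use; configurable), Downstream is 3 kb past
the TES, and UTRs are exonic sequence outside the BED12 thick (CDS)
region. Midpoint assignment — rather than any-overlap — guarantees a
single unambiguous category per peak; a peak whose midpoint lies in *any*
gene's promoter window is Promoter regardless of what else it touches.
Ties within a category go to the nearest TSS, then lexicographic gene id.
Distal peaks are credited to the nearest gene's "other" signal only within
100 kb (configurable); beyond that they are dropped from the
promoter+other conservation. All coordinates are 0-based half-open
throughout, so BED files are read and written without shifting.

Per gene, promoter signal $P$ and all other assigned signal $O$ are tested
separately with the same gated engine (spike-in calibrated), giving two
trits $(dP, dO)$ per comparison and the shift partition:

* `Type1` $(+1, -1)$ — promoter gain, other-region loss;
* `Type2` $(-1, +1)$ — the mirror;
* `None` $(0, 0)$;
* `Type3` — the remaining six cells.

The direction convention (which of the two opposing shifts is "Type 1") is
a label choice, not a finding; it follows the order in which the source
describes the two cases. Gating both regions on significance is likewise a
declared choice — the alternative (raw count direction) is not exposed.

## Concordance (a-DEGs) and enrichment

A gene is an **a-DEG** for one (comparison, lobe) when its RNA gated
change and its promoter-H3K27ac gated change are both nonzero *and* share
a sign — i.e. significant in both assays, same direction, no magnitude
threshold. By construction the a-DEG set is a subset of the intersection
of the two gated DEG sets; planted same-sign effects are recovered
completely at strong effect and depth while opposite-sign planting yields
zero a-DEGs (both tested).

Preranked GSEA ranks genes by gated $g$ (zeros excluded — the ranked list
*is* the significant genes, which is what "enrichment on the DEGs" means
here), ties broken lexicographically. The classic weighted running-sum ES
($p = 1$: hits add $|g|^p$ normalized by the in-set total, misses subtract
$1/(N - N_{\mathrm{hits}})$) is checked against an independent brute-force
implementation on all small lists. The null for NES is **gene-set
permutation** (random same-size sets from the ranked universe), because
the pipeline consumes ranked lists rather than raw phenotype matrices;
$\mathrm{NES} = ES / \overline{|ES_{\mathrm{null}}|}$ over same-sign null
draws, with an empirical same-sign $p$ and BH across sets. A set whose
sign has no null mass is flagged rather than forced.

Per-cell scoring uses a single-sample rank-walk statistic (the ssGSEA
family): genes are ranked within each cell, and the score sums the gap
between the rank-weighted in-set ECDF (weights $\mathrm{rank}^{0.25}$) and
the unweighted out-of-set ECDF. It depends only on ranks, hence is
invariant under any strictly monotone transform of expression — a property
the tests exercise directly — and is deterministic. One compositional
caveat matters for interpretation: because scores are functions of ranks,
raising one gene set's expression *depresses* the scores of disjoint sets
in the same cells; disjoint "neutral" sets are therefore expected to show
mild opposite-direction shifts when a planted set moves.

## Single-cell stage

Cells are flagged by the standard printed QC bounds — features outside
[400, 7000], total counts outside [500, 80000], mitochondrial fraction
above 15%, ribosomal fraction above 40% — all configurable. Marker testing
is a two-sided Wilcoxon rank-sum on log-normalized expression, restricted
to genes detected in ≥ 30% of at least one group (`min_pct`), BH-adjusted;
for small untied samples the p value is exact and matches an exhaustive
permutation oracle.

Stratification: the signature score is the mean of per-gene standardized
log-normalized expression over the 16 signature genes (no control-bin
correction — a deliberate simplification), and cells split at the median
with ties going low (the split quantile is exposed because the source
does not state it). Within each cell type, per-cell pathway scores are
compared high vs low with a Welch t test, BH-adjusted across pathways
within the cell type, and the t statistic is zeroed wherever
$p_{\mathrm{adj}} > 0.05$ — the same gating idea as $g_{ij}$, applied to t
values.

One statistical point deserves emphasis: a *data-derived* median split is
selection-biased even under a global null, because the same counts choose
the strata and feed the pathway scores — pathways overlapping the
signature inherit a spurious positive shift and disjoint pathways a
compositional negative one. The all-zeros null property therefore holds
for *exchangeable* strata (e.g. the generator's planted labels under a
zero effect), which is how the calibration test is built; the
planted-direction test uses the full data-derived pipeline. When
interpreting real gated-t matrices, the signature-containing pathway's own
row should be read as confirmatory, not inferential.

## The synthetic-data generator

The generator is first-class, tested code; every downstream stage is
validated against its planted truth.

* **Bulk** (`sim_bulk`): negative binomial counts with variance
  $\mu + \varphi\mu^2$, default $\varphi = 0.1$ (a mid-range biological CV
  for bulk RNA), over 4 groups × 5 lobes × 3 replicates — the study's
  design. Gene baseline means are log-uniform over
  $[\mathrm{depth}/16,\ 16\,\mathrm{depth}]$ with depth $10^4$, and
  per-sample size factors are log-uniform in $[0.5, 2]$ so normalization
  is always exercised. Trend labels (60% NE, 10% each of the four effect
  classes, $|\log_2\mathrm{FC}| = 2.5$) are planted *through the rule
  table itself*: `trend_offsets()` converts labels to canonical group
  offsets and asserts that the implied sign pattern classifies back to the
  planted label, so generator and classifier cannot drift apart.
* **Chromatin** (`sim_chromatin`): per-gene promoter/other NB counts with
  a 0.6 baseline promoter share, planted Type1/Type2 genes shifting
  ±1 log2 in opposite directions between the contrasted groups, Poisson
  spike-in reads proportional to each library's scale. Default dispersion
  is 0.01 (replicate CV 10%), tighter than the bulk default: the signal
  here is aggregated over whole promoter windows and gene bodies and
  spike-calibrated, and the recoverability requirement on planted 2-fold
  shifts at $n = 3$ with a per-gene test (no shrinkage) pins the realistic
  noise regime to about this level.
* **Single cell** (`sim_sc`): eight lung cell types with canonical markers
  elevated only in their own type, a planted high/low signature stratum,
  and an exact planted fraction of QC outliers, each violating at least
  one printed bound. QC metrics are generated per cell rather than derived
  from the matrix — a simplification that makes the QC truth exact.

What the generator does **not** emulate: gene–gene correlation, batch
effects beyond size factors, single-cell dropout beyond Poisson sampling,
doublets, real pathway structure, or any feature of the deposited
sequencing data. Passing tests therefore demonstrate that the *methods*
recover what was planted under their own model assumptions at realistic
noise — not that the original study's gene lists would be reproduced.
The study's headline counts derive from its deposited sequencing data and
are out of reach at desk scale by design.

## Determinism and numerics

Every simulator takes a single seed and derives per-component sub-streams
deterministically; identical (parameters, seed) give byte-identical files,
and `run_pipeline()` run twice on the same bundle produces byte-identical
outputs (hash-checked in tests; the manifest records seeds and parameters
and deliberately no timestamps). Numerical conventions: dispersion floor
$10^{-8}$; pseudocount 0.5 on normalized means; all-zero genes get
$p = 1$; GSEA ties break lexicographically; stratification ties go low;
empty BED files parse to empty tables with a message rather than an error.

Problem sizes in the test suite — 1000–2000 genes, 3 replicates, 200-gene
chromatin panels, 2000 cells, 200 random annotation genomes, 500 random
GSEA lists, 1000 BH vectors, 20 seeded stratification runs — were chosen
as the smallest sizes at which the Monte-Carlo bands in the tests are
comfortably stable.

## Known limitations

* No dispersion shrinkage, independent filtering or outlier replacement;
  at $n = 3$ the per-gene engine is honest but not maximally powerful.
* The rank-walk score has the compositional coupling noted above.
* The taxonomy's `Rein01`/`Rein02` boundary and the Type1/Type2 direction
  are declared conventions over an under-specified source; both are
  configuration, and conclusions that depend on the boundary should be
  checked under the alternative table.
* The annotation assigns one category per peak by midpoint; peaks
  straddling features are not split.
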