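Package: lobeomics
Title: Multiomics Trend Classification and Promoter-Shift Analysis for
    Treatment Studies Across Lung Lobes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated analysis of bulk transcriptomes and
    H3K27ac chromatin signal across anatomical units (lung lobes) in
    four-arm treatment designs (control, disease, vehicle, treatment).
    Implements significance-gated signed fold changes from a negative
    binomial Wald test, a configurable five-type trend taxonomy over
    multi-comparison sign patterns, spike-in calibration and
    promoter-precedence annotation of chromatin signal with
    promoter-to-other shift typing, transcriptome/chromatin concordance
    (a-DEGs), preranked gene-set enrichment with per-sample rank-walk
    scores, and signature-based stratification of single cells with
    gated t statistics. Ships a seeded synthetic-data generator with
    planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
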