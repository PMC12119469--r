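#' Accordant differential genes (a-DEGs)
#'
#' A gene is an a-DEG for one (comparison, lobe) when its gated change is
#' nonzero in both the transcriptome and the promoter chromatin result and
#' the two changes share a sign. Concordance is decided on the gated
#' changes — both assays significant — with no magnitude threshold.
#'
#' @param rna,prom Comparison-result tibbles for the same comparison and
#'   lobe (gene universes are intersected by `gene_id`).
#' @return Tibble: `gene_id`, `comparison`, `lobe`, `rna_g`, `prom_g`,
#'   `direction` (`up`/`down`).
#' @export
find_adegs <- function(rna, prom) {
  if (!identical(unique(rna$comparison), unique(prom$comparison))) {
    abort(sprintf("comparison labels differ: %s vs %s",
                  paste(unique(rna$comparison), collapse = ","),
                  paste(unique(prom$comparison), collapse = ",")))
  }
  merged <- dplyr::inner_join(
    dplyr::select(as_tibble(rna), "gene_id", "comparison", "lobe", rna_g = "g"),
    dplyr::select(as_tibble(prom), "gene_id", prom_g = "g"),
    by = "gene_id")
  merged |>
    dplyr::filter(.data$rna_g != 0, .data$prom_g != 0,
                  sign(.data$rna_g) == sign(.data$prom_g)) |>
    dplyr::mutate(direction = ifelse(.data$rna_g > 0, "up", "down")) |>
    dplyr::arrange(.data$gene_id)
}

#' Overlap a-DEGs with trend-label gene sets
#'
#' Counts, for each supplied gene set (e.g. the shared Rein02 set and the
#' lobe-specific Rein02 sets), how many a-DEGs fall in it; a gene is
#' counted once per set it belongs to.
#'
#' @param adegs a-DEG tibble from [find_adegs()].
#' @param sets Named list of character gene sets.
#' @return List: `counts` (tibble `set`, `n_set`, `n_overlap`) and
#'   `genes` (named list of overlapping gene ids).
#' @export
overlap_with_labels <- function(adegs, sets) {
  if (is.null(names(sets))) abort("sets must be named")
  genes <- purrr::map(sets, function(s) sort(intersect(adegs$gene_id, s)))
  counts <- tibble(set = names(sets),
                   n_set = unname(purrr::map_int(sets, length)),
                   n_overlap = unname(purrr::map_int(genes, length)))
  list(counts = counts, genes = genes)
}
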