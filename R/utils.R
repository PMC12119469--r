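#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols across all_of any_of n
#'   row_number distinct pull rename relocate first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr map_lgl imap
#'   list_rbind walk
#' @importFrom stats pnorm pt qnorm p.adjust median quantile rnbinom rpois
#'   rbinom runif rnorm sd var t.test wilcox.test setNames
#' @importFrom utils head tail
NULL

GROUPS <- c("C", "G", "P", "M")
LOBES <- c("H", "L", "R1", "R2", "R3")
COMPARISONS <- c("GvC", "MvG", "PvG", "MvP")

# Derive a reproducible 32-bit sub-seed from a top-level seed and a stream
# label, so each simulator component draws from its own deterministic stream.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * (31^(seq_along(utf8ToInt(as.character(stream))) %% 7)))
  as.integer((abs(seed) * 48271 + h) %% 2147483647L)
}

# counts tibble -> integer matrix with gene_id rownames
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "gene_id")
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene_id
  m
}

matrix_to_counts <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
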