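#' Default trend rule table
#'
#' The five-type taxonomy over sign patterns of the gated changes
#' (`s_GvC`, `s_MvG`, `s_PvG`, `s_MvP`, each in -1/0/+1). Rules are rows
#' evaluated top-down; the first match wins and a trailing wildcard row
#' supplies the fallback. Trits are written `"+"`, `"-"`, `"0"` with `"*"`
#' as wildcard, so the table round-trips through a plain TSV config.
#'
#' Semantics of the default table: `Rein02` — the treatment effect (MvG)
#' reverses the disease trend while the vehicle does not (PvG not opposite
#' to GvC, or disease-silent genes whose vehicle trend is reversed by
#' treatment); `Rein01` — both treatment and vehicle reverse the disease
#' trend; `SR` — vehicle reverses with no treatment effect (self-recovery);
#' `Whip01` — treatment moves with the disease trend (exacerbation);
#' `NE` — everything else, including the all-zero pattern. `s_MvP` is kept
#' in patterns for custom tables but unused by the defaults.
#'
#' @return Tibble: `label`, `s_GvC`, `s_MvG`, `s_PvG`, `s_MvP`.
#' @export
default_trend_rules <- function() {
  tibble::tribble(
    ~label,    ~s_GvC, ~s_MvG, ~s_PvG, ~s_MvP,
    "Rein02",  "+",    "-",    "0",    "*",
    "Rein02",  "+",    "-",    "+",    "*",
    "Rein02",  "-",    "+",    "0",    "*",
    "Rein02",  "-",    "+",    "-",    "*",
    "Rein02",  "0",    "-",    "+",    "*",
    "Rein02",  "0",    "+",    "-",    "*",
    "Rein01",  "+",    "-",    "-",    "*",
    "Rein01",  "-",    "+",    "+",    "*",
    "SR",      "+",    "0",    "-",    "*",
    "SR",      "-",    "0",    "+",    "*",
    "Whip01",  "+",    "+",    "*",    "*",
    "Whip01",  "-",    "-",    "*",    "*",
    "NE",      "*",    "*",    "*",    "*"
  )
}

#' @rdname default_trend_rules
#' @param path TSV with the rule-table columns, rules in priority order.
#' @export
read_trend_rules <- function(path) {
  rules <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  validate_trend_rules(rules)
}

#' @rdname default_trend_rules
#' @param rules Rule tibble to validate (totality over all 81 patterns).
#' @export
validate_trend_rules <- function(rules) {
  need <- c("label", "s_GvC", "s_MvG", "s_PvG", "s_MvP")
  if (!all(need %in% names(rules))) {
    abort(paste0("rule table needs columns: ", paste(need, collapse = ", ")))
  }
  ok_trit <- c("+", "-", "0", "*")
  for (col in need[-1]) {
    bad <- setdiff(unique(rules[[col]]), ok_trit)
    if (length(bad)) abort(sprintf("invalid trit '%s' in %s", bad[1], col))
  }
  grid <- all_sign_patterns()
  lab <- classify_trend(grid, rules, .validate = FALSE)
  if (anyNA(lab)) {
    miss <- grid[which(is.na(lab))[1], ]
    abort(sprintf("rule table does not cover pattern (%d,%d,%d,%d) and has no fallback",
                  miss$s_GvC, miss$s_MvG, miss$s_PvG, miss$s_MvP))
  }
  as_tibble(rules)
}

#' @rdname default_trend_rules
#' @export
write_trend_rules <- function(rules, path) {
  readr::write_tsv(rules, path, progress = FALSE)
  invisible(path)
}

# all 81 trit patterns, as a tibble of integers
all_sign_patterns <- function() {
  tidyr::expand_grid(s_GvC = c(-1L, 0L, 1L), s_MvG = c(-1L, 0L, 1L),
                     s_PvG = c(-1L, 0L, 1L), s_MvP = c(-1L, 0L, 1L))
}

trit_matches <- function(pattern_num, rule_trit) {
  rule_trit == "*" |
    (rule_trit == "+" & pattern_num == 1L) |
    (rule_trit == "-" & pattern_num == -1L) |
    (rule_trit == "0" & pattern_num == 0L)
}

#' Classify sign patterns into trend labels
#'
#' @param patterns Tibble with integer columns `s_GvC`, `s_MvG`, `s_PvG`,
#'   `s_MvP` (values in -1, 0, +1).
#' @param rules Rule table; first matching row wins.
#' @param .validate Internal: skip re-validation.
#' @return Character vector of labels, one per pattern row.
#' @export
classify_trend <- function(patterns, rules = default_trend_rules(),
                           .validate = TRUE) {
  if (.validate) rules <- validate_trend_rules(rules)
  lab <- rep(NA_character_, nrow(patterns))
  for (r in seq_len(nrow(rules))) {
    hit <- is.na(lab) &
      trit_matches(patterns$s_GvC, rules$s_GvC[r]) &
      trit_matches(patterns$s_MvG, rules$s_MvG[r]) &
      trit_matches(patterns$s_PvG, rules$s_PvG[r]) &
      trit_matches(patterns$s_MvP, rules$s_MvP[r])
    lab[hit] <- rules$label[r]
  }
  lab
}

#' Per-gene sign patterns from gated comparison results
#'
#' @param results Stacked comparison-result tibble for one lobe containing
#'   all four comparisons (`GvC`, `MvG`, `PvG`, `MvP`).
#' @return Tibble: `gene_id`, `s_GvC`, `s_MvG`, `s_PvG`, `s_MvP`.
#' @export
sign_pattern <- function(results) {
  have <- unique(results$comparison)
  missing <- setdiff(COMPARISONS, have)
  if (length(missing)) {
    abort(paste0("missing comparison(s): ", paste(missing, collapse = ", ")))
  }
  wide <- results |>
    dplyr::select("gene_id", "comparison", "g") |>
    dplyr::mutate(s = sign(.data$g)) |>
    dplyr::select(-"g") |>
    tidyr::pivot_wider(names_from = "comparison", values_from = "s",
                       names_prefix = "s_")
  if (anyNA(wide)) abort("some genes lack a result in one or more comparisons")
  wide |>
    dplyr::mutate(across(dplyr::starts_with("s_"), as.integer)) |>
    dplyr::select("gene_id", all_of(paste0("s_", COMPARISONS)))
}

#' Assign trend labels per gene and lobe
#'
#' @param results Stacked comparison results over lobes and comparisons.
#' @param rules Trend rule table.
#' @return Tibble: `gene_id`, `lobe`, the four trits, `label`.
#' @export
assign_trends <- function(results, rules = default_trend_rules()) {
  rules <- validate_trend_rules(rules)
  results |>
    dplyr::group_split(.data$lobe) |>
    purrr::map(function(chunk) {
      pat <- sign_pattern(chunk)
      pat$lobe <- chunk$lobe[1]
      pat$label <- classify_trend(pat, rules, .validate = FALSE)
      dplyr::relocate(pat, "lobe", .after = "gene_id")
    }) |>
    list_rbind()
}

#' Shared and lobe-specific gene sets
#'
#' Given per-lobe gene sets (for example the Rein02 genes of each lobe),
#' computes the shared set (present in every lobe), the lobe-specific sets
#' (present in exactly one lobe) and the full count of every non-empty
#' membership class over the lobes (UpSet-style).
#'
#' @param sets Named list of character vectors, one per lobe.
#' @return List with `shared`, `specific` (named list) and `classes`
#'   (tibble: one row per membership combination with `n_lobes`, `count`
#'   and logical membership columns).
#' @export
shared_specific <- function(sets) {
  if (length(sets) < 2) abort("need at least 2 lobes")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) abort("sets must be named by lobe")
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  shared <- universe[rowSums(member) == length(sets)]
  specific <- purrr::imap(sets, function(s, nm) {
    universe[member[, nm] & rowSums(member) == 1]
  })
  classes <- tibble(key = key) |>
    dplyr::count(.data$key, name = "count")
  memb_cols <- do.call(rbind, strsplit(classes$key, "")) == "1"
  colnames(memb_cols) <- names(sets)
  classes <- dplyr::bind_cols(as_tibble(memb_cols), classes["count"]) |>
    dplyr::mutate(n_lobes = rowSums(memb_cols), .before = "count") |>
    dplyr::arrange(dplyr::desc(.data$n_lobes), dplyr::desc(.data$count))
  list(shared = shared, specific = specific, classes = classes)
}
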