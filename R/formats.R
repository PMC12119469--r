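#' Read and validate a sample sheet
#'
#' The sample sheet describes the bulk design: one row per sequencing
#' library with its treatment group (`C` control, `G` disease, `P` vehicle,
#' `M` treatment), lung lobe (`H`, `L`, `R1`, `R2`, `R3`), replicate index
#' and, for chromatin libraries, the number of reads mapping to the
#' exogenous spike-in genome.
#'
#' @param path CSV file with columns `sample_id`, `group`, `lobe`,
#'   `replicate` and optionally `spike_in_reads`.
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  ss <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(ss)
}

#' @rdname read_sample_sheet
#' @param samples A data frame to validate in place.
#' @export
validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "group", "lobe", "replicate")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    abort(paste0("sample sheet lacks column(s): ", paste(missing, collapse = ", ")))
  }
  samples <- as_tibble(samples)
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample_id in sample sheet")
  }
  bad_g <- setdiff(unique(samples$group), GROUPS)
  if (length(bad_g)) abort(paste0("unknown group(s): ", paste(bad_g, collapse = ", ")))
  bad_l <- setdiff(unique(samples$lobe), LOBES)
  if (length(bad_l)) abort(paste0("unknown lobe(s): ", paste(bad_l, collapse = ", ")))
  if (any(samples$replicate < 1 | samples$replicate != round(samples$replicate))) {
    abort("replicate must be a positive integer")
  }
  if ("spike_in_reads" %in% names(samples) &&
      any(!is.na(samples$spike_in_reads) & samples$spike_in_reads < 0)) {
    abort("spike_in_reads must be nonnegative")
  }
  samples
}

#' Read a gene-by-sample count table
#'
#' Counts are read from a TSV whose first column is `gene_id` and whose
#' remaining columns are sample libraries. Cells must be nonnegative
#' integers; violations are reported with the offending gene and sample.
#'
#' @param path TSV file path.
#' @param samples Sample sheet tibble; every `sample_id` must appear in the
#'   header, and the returned columns follow sheet order.
#' @return Tibble: `gene_id` plus one numeric column per sample.
#' @export
read_count_matrix <- function(path, samples) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "gene_id") names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  validate_count_matrix(x, samples)
}

#' @rdname read_count_matrix
#' @param counts Count tibble (`gene_id` first) to validate.
#' @export
validate_count_matrix <- function(counts, samples = NULL) {
  counts <- as_tibble(counts)
  if (anyDuplicated(counts$gene_id)) abort("duplicate gene_id in count table")
  if (!is.null(samples)) {
    absent <- setdiff(samples$sample_id, names(counts))
    if (length(absent)) {
      abort(paste0("sample(s) in sheet missing from count table: ",
                   paste(absent, collapse = ", ")))
    }
    counts <- counts[, c("gene_id", samples$sample_id)]
  }
  m <- counts_to_matrix(counts)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "count table cell is not a nonnegative integer: gene %s, sample %s (value %s)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]]))
  }
  counts
}

#' Write a count table
#' @param counts Count tibble (`gene_id` first column).
#' @param path Output TSV path.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(dplyr::arrange(counts, .data$gene_id), path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: tab-separated lines of set name, description, then
#' member genes. Duplicate genes within a line are dropped with a warning;
#' duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return Tibble with columns `set_name`, `description` and list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort(sprintf("GMT line %d has fewer than 3 fields", i))
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warn(sprintf("GMT set '%s' (line %d): duplicate genes deduplicated", f[1], i))
      genes <- unique(genes)
    }
    tibble(set_name = f[1], description = f[2], genes = list(genes))
  })
  out <- list_rbind(rows)
  if (anyDuplicated(out$set_name)) {
    dup <- out$set_name[duplicated(out$set_name)][1]
    abort(sprintf("duplicate gene-set name in GMT: '%s'", dup))
  }
  out
}

#' @rdname read_gmt
#' @param sets Gene-set tibble as returned by `read_gmt()`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(set_name, description, genes, ...) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

# named list form, convenient for the enrichment code
gene_set_list <- function(sets) setNames(sets$genes, sets$set_name)

#' Read BED3+ peak intervals
#'
#' Intervals stay in BED-native 0-based half-open coordinates; no shifting
#' is ever applied internally.
#'
#' @param path BED file (>= 3 columns; optional 4th name, 5th score).
#' @param sample_id Library the peaks belong to.
#' @return Tibble: `chrom`, `start`, `end`, `score`, `sample_id`.
#' @export
read_bed_peaks <- function(path, sample_id) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    inform(sprintf("empty BED file: %s", path))
    return(tibble(chrom = character(), start = double(), end = double(),
                  score = double(), sample_id = character()))
  }
  rows <- purrr::imap(lines, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort(sprintf("BED line %d has fewer than 3 columns", i))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != round(s) || e != round(e)) {
      abort(sprintf("BED line %d: non-integral coordinates", i))
    }
    if (s >= e) abort(sprintf("BED line %d: start >= end (%s >= %s)", i, f[2], f[3]))
    tibble(chrom = f[1], start = s, end = e,
           score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_)
  })
  out <- list_rbind(rows)
  out$sample_id <- sample_id
  out
}

#' @rdname read_bed_peaks
#' @param peaks Peak tibble.
#' @export
write_bed_peaks <- function(peaks, path) {
  peaks <- dplyr::arrange(peaks, .data$chrom, .data$start, .data$end)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end),
                   if (nrow(peaks)) paste0("peak", seq_len(nrow(peaks))) else character(),
                   ifelse(is.na(peaks$score), "0", format(peaks$score, trim = TRUE, scientific = FALSE)))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read BED12 gene models
#'
#' Parses exon block structure into explicit half-open exon intervals and
#' keeps the thick (CDS) region, which later distinguishes UTR from coding
#' exon during annotation. Exons must be sorted, non-overlapping and
#' contained in the gene span.
#'
#' @param path BED12 file.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `thick_start`, `thick_end`, and list-column `exons` (two-column
#'   matrices of half-open intervals).
#' @export
read_gene_models_bed12 <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) abort(sprintf("BED12 line %d has %d < 12 columns", i, length(f)))
    start <- as.numeric(f[2]); end <- as.numeric(f[3])
    if (start >= end) abort(sprintf("BED12 line %d: start >= end", i))
    n_blocks <- as.integer(f[10])
    sizes <- as.numeric(strsplit(sub(",$", "", f[11]), ",", fixed = TRUE)[[1]])
    offs <- as.numeric(strsplit(sub(",$", "", f[12]), ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      abort(sprintf("BED12 line %d: blockCount=%d but %d sizes / %d starts",
                    i, n_blocks, length(sizes), length(offs)))
    }
    exons <- cbind(start = start + offs, end = start + offs + sizes)
    validate_gene_model(f[4], start, end, exons, line = i)
    tibble(gene_id = f[4], chrom = f[1], start = start, end = end,
           strand = f[6], thick_start = as.numeric(f[7]),
           thick_end = as.numeric(f[8]), exons = list(exons))
  })
  out <- list_rbind(rows)
  if (anyDuplicated(out$gene_id)) abort("duplicate gene_id in gene models")
  if (!all(out$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  out
}

validate_gene_model <- function(gene_id, start, end, exons, line = NA) {
  ok <- nrow(exons) >= 1 &&
    all(exons[, 1] < exons[, 2]) &&
    all(exons[, 1] >= start) && all(exons[, 2] <= end) &&
    (nrow(exons) == 1 || all(diff(exons[, 1]) > 0)) &&
    (nrow(exons) == 1 || all(exons[-nrow(exons), 2] <= exons[-1, 1]))
  if (!ok) {
    abort(sprintf("gene model '%s'%s: exons must be sorted, non-overlapping, within the span",
                  gene_id, if (is.na(line)) "" else sprintf(" (line %d)", line)))
  }
  invisible(TRUE)
}

#' @rdname read_gene_models_bed12
#' @param models Gene-model tibble.
#' @export
write_gene_models_bed12 <- function(models, path) {
  models <- dplyr::arrange(models, .data$gene_id)
  lines <- purrr::pmap_chr(models, function(gene_id, chrom, start, end, strand,
                                            thick_start, thick_end, exons, ...) {
    sizes <- exons[, 2] - exons[, 1]
    offs <- exons[, 1] - start
    paste(chrom, format(start, scientific = FALSE, trim = TRUE),
          format(end, scientific = FALSE, trim = TRUE), gene_id, "0", strand,
          format(thick_start, scientific = FALSE, trim = TRUE),
          format(thick_end, scientific = FALSE, trim = TRUE), "0",
          nrow(exons),
          paste0(paste(format(sizes, scientific = FALSE, trim = TRUE), collapse = ","), ","),
          paste0(paste(format(offs, scientific = FALSE, trim = TRUE), collapse = ","), ","),
          sep = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a result table deterministically
#'
#' Rows are sorted by `gene_id` then by any other key columns present
#' (`sample_id`, `comparison`, `lobe`, `set_name`), columns keep their
#' order, so two writes of equal tables are byte-identical.
#'
#' @param table A data frame.
#' @param path Output TSV path.
#' @export
write_results_tsv <- function(table, path) {
  keys <- intersect(c("gene_id", "sample_id", "comparison", "lobe",
                      "set_name", "cell_id", "cell_type", "pathway"),
                    names(table))
  if (length(keys)) {
    table <- dplyr::arrange(table, dplyr::across(all_of(keys)))
  }
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}
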