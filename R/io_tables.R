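# TSV table I/O (isoforms, closed-loop groups, external dTE tables, counts)
# and the dominant-isoform rule.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, cols, what) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  check_columns(df, cols, what)
  df
}

#' Read/write an isoform-abundance table
#'
#' Columns: gene_id, isoform_id, tl_length (nt), relative_abundance.
#' Per gene, abundances must be non-negative and sum to at most 1 + 1e-6.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_isoforms <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "isoform_id", "tl_length",
                                 "relative_abundance"), "isoform table")
  if (any(df$relative_abundance < 0)) {
    ribote_stop("isoform table: negative relative_abundance")
  }
  sums <- tapply(df$relative_abundance, df$gene_id, sum)
  if (any(sums > 1 + 1e-6)) {
    ribote_stop(sprintf(
      "isoform table: abundances of gene(s) %s sum to more than 1",
      paste(head(names(sums)[sums > 1 + 1e-6], 5), collapse = ", ")))
  }
  df
}

#' @rdname read_isoforms
#' @param df isoform data.frame.
#' @export
write_isoforms <- function(df, path) write_tsv(df, path)

#' Select the dominant transcript-leader isoform per gene
#'
#' A gene has a dominant isoform when, after renormalizing its abundances to
#' sum to 1, the top isoform accounts for at least 40% of transcripts and is
#' at least twice as abundant as the next most abundant isoform ("at least":
#' ties at exactly 40% or exactly 2x pass). Single-isoform genes pass iff
#' their renormalized abundance is >= 40%. Genes failing the rule map to
#' `NA`.
#'
#' @param isoforms isoform table (see [read_isoforms()]).
#' @param min_fraction dominance threshold on the top isoform (default 0.40).
#' @param min_ratio required ratio of top to second abundance (default 2).
#' @return named numeric vector: gene_id -> TL length of the dominant
#'   isoform, `NA` where no isoform qualifies.
#' @export
select_dominant_isoform <- function(isoforms, min_fraction = 0.40,
                                    min_ratio = 2) {
  check_columns(isoforms, c("gene_id", "isoform_id", "tl_length",
                            "relative_abundance"), "isoform table")
  genes <- unique(isoforms$gene_id)
  out <- setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    sub <- isoforms[isoforms$gene_id == g, , drop = FALSE]
    ab <- sub$relative_abundance
    tot <- sum(ab)
    if (tot <= 0) next
    ab <- ab / tot  # rule is stated in fractions of all transcripts
    o <- order(ab, decreasing = TRUE)
    top <- ab[o[1]]
    second <- if (length(ab) >= 2) ab[o[2]] else 0
    if (top >= min_fraction && top >= min_ratio * second) {
      out[g] <- sub$tl_length[o[1]]
    }
  }
  out
}

#' Read closed-loop group assignments
#'
#' Columns: gene_id, group; groups must be in 1..4 (group 3 = strong
#' closed-loop potential).
#' @param path TSV path.
#' @return data.frame(gene_id, group).
#' @export
read_closed_loop <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "group"), "closed-loop table")
  if (!all(df$group %in% 1:4)) {
    ribote_stop(sprintf(
      "closed-loop table: invalid group label(s): %s (must be 1-4)",
      paste(head(unique(df$group[!df$group %in% 1:4]), 5), collapse = ", ")))
  }
  df
}

#' Read an external dTE table from another factor mutant
#'
#' Columns: gene_id, log2_dte. Duplicate gene ids are resolved last-wins with
#' a warning.
#' @param path TSV path.
#' @return data.frame(gene_id, log2_dte), one row per gene.
#' @export
read_external_dte <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "log2_dte"), "external dTE table")
  dup <- duplicated(df$gene_id, fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf(
      "external dTE table: %d duplicate gene id(s); keeping the last occurrence",
      sum(dup)), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Read/write position-level footprint counts
#'
#' Long-format TSV: transcript_id, position (0-based nt), sample_id, count.
#' @param path TSV path.
#' @param ann optional `annotation_set`; when given, positions are validated
#'   against transcript lengths (hard error on violation).
#' @return a `position_counts` data.table.
#' @export
read_position_counts <- function(path, ann = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  check_columns(dt, c("transcript_id", "position", "sample_id", "count"),
                "position counts")
  if (any(dt$count < 0) || any(dt$count != round(dt$count))) {
    ribote_stop("position counts: counts must be non-negative integers")
  }
  if (!is.null(ann)) validate_positions(dt, ann)
  data.table::setkeyv(dt, c("transcript_id", "position", "sample_id"))
  class(dt) <- c("position_counts", class(dt)[class(dt) != "position_counts"])
  dt
}

#' @rdname read_position_counts
#' @param pos `position_counts` table.
#' @export
write_position_counts <- function(pos, path) {
  data.table::fwrite(pos, path, sep = "\t")
  invisible(path)
}

validate_positions <- function(pos, ann) {
  len <- ann$transcripts$tx_length[
    match(pos$transcript_id, ann$transcripts$transcript_id)]
  bad <- is.na(len) | pos$position < 0 | pos$position >= len
  if (any(bad)) {
    ribote_stop(sprintf(
      "position counts: %d record(s) outside annotated transcripts (first: %s pos %d) - corrupt input",
      sum(bad), pos$transcript_id[which(bad)[1]], pos$position[which(bad)[1]]),
      class = "ribote_corrupt_input")
  }
  invisible(pos)
}

#' Read/write a gene-level count matrix with sample metadata
#'
#' The TSV carries one gene_id column plus one column per sample; sample
#' metadata (condition, replicate) is parsed from column names of the form
#' `WT_1`, `MUT_2`, ...
#'
#' @param path TSV path.
#' @param assay_type "RP" or "RNA".
#' @return a [count_matrix()] SummarizedExperiment.
#' @export
read_count_table <- function(path, assay_type) {
  df <- read_tsv_checked(path, "gene_id", "count table")
  samples <- setdiff(names(df), "gene_id")
  parsed <- regmatches(samples, regexec("^(WT|MUT)_([0-9]+)$", samples))
  ok <- lengths(parsed) == 3
  if (!all(ok)) {
    ribote_stop(sprintf(
      "count table: sample column(s) not of the form WT_<i>/MUT_<i>: %s",
      paste(samples[!ok], collapse = ", ")), class = "ribote_schema_error")
  }
  mat <- as.matrix(df[, samples, drop = FALSE])
  rownames(mat) <- df$gene_id
  count_matrix(mat, assay_type,
               condition = vapply(parsed, `[`, character(1), 2),
               replicate = as.integer(vapply(parsed, `[`, character(1), 3)))
}

#' @rdname read_count_table
#' @param se a [count_matrix()] SummarizedExperiment.
#' @export
write_count_table <- function(se, path) {
  mat <- cm_counts(se)
  write_tsv(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
            path)
}

#' Read/write a simulation truth table
#' @param path TSV path.
#' @return truth data.frame.
#' @export
read_truth <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "true_log2_dte", "is_null"),
                         "truth table")
  class(df) <- c("truth_table", "data.frame")
  df
}

#' @rdname read_truth
#' @param truth truth table.
#' @export
write_truth <- function(truth, path) write_tsv(truth, path)
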