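# Footprint quantification: codon-exclusion window, CDS and uORF counting,
# and the low-expression mRNA filter.

#' Codon counting window for a CDS
#'
#' Footprints mapping to the initial 15 codons and the final 5 codons of a
#' CDS are excluded to avoid cycloheximide-induced artifacts near the start
#' and stop codons. Returns the 0-based half-open codon interval
#' `[15, L - 5)`; the interval is empty when `L <= 20`, signalling that the
#' gene is not quantifiable.
#'
#' @param cds_length_codons CDS length in codons (>= 1).
#' @return integer vector `c(start, end)`, half-open; `end <= start` means
#'   empty.
#' @examples
#' cds_counting_window(100)  # 15 95: 80 codons counted
#' cds_counting_window(20)   # empty
#' @export
cds_counting_window <- function(cds_length_codons) {
  stopifnot(is_count(cds_length_codons), cds_length_codons >= 1)
  L <- as.integer(cds_length_codons)
  c(start = 15L, end = max(15L, L - 5L))
}

#' Count CDS footprints under the codon-exclusion rule
#'
#' Sums position-level footprint counts whose codon index
#' `floor((position - cds_start) / 3)` falls inside [cds_counting_window()].
#' Genes whose window is empty (CDS <= 20 codons) are dropped with a message.
#' Positions outside any annotated transcript are a hard error (corrupt
#' input); positions in the TL or 3'-UTR contribute to no gene.
#'
#' @param pos a `position_counts` table.
#' @param ann an `annotation_set`.
#' @param condition,replicate optional per-sample metadata; by default parsed
#'   from sample ids of the form `WT_1`/`MUT_2`.
#' @return a [count_matrix()] SummarizedExperiment (assay_type "RP") with one
#'   row per quantifiable gene.
#' @export
count_cds <- function(pos, ann, condition = NULL, replicate = NULL) {
  validate_positions(pos, ann)
  tr <- ann$transcripts
  dt <- data.table::as.data.table(pos)
  key <- data.table::data.table(
    transcript_id = tr$transcript_id, gene_id = tr$gene_id,
    cds_start = tr$cds_start, cds_codons = tr$cds_length %/% 3L
  )
  dt <- merge(dt, key, by = "transcript_id")
  dt[, codon := (position - cds_start) %/% 3L]
  win_lo <- 15L
  dt[, win_hi := pmax(15L, cds_codons - 5L)]
  dt <- dt[position >= cds_start & codon >= win_lo & codon < win_hi]
  agg <- dt[, list(count = sum(count)), by = c("gene_id", "sample_id")]

  empty <- key$gene_id[key$cds_codons <= 20L]
  if (length(empty) > 0) {
    message(sprintf(
      "count_cds: dropped %d gene(s) with CDS <= 20 codons (empty counting window)",
      length(empty)))
  }
  genes <- setdiff(tr$gene_id, empty)
  samples <- sort(unique(as.character(pos$sample_id)))
  build_count_se(agg, genes, samples, "RP", condition, replicate)
}

#' Count uORF footprints over their full length
#'
#' uORFs are too short for the codon-exclusion rule, so their footprints are
#' summed over the full uORF interval with no exclusion.
#'
#' @inheritParams count_cds
#' @return a [count_matrix()] SummarizedExperiment (assay_type "RP") with one
#'   row per uORF (rowData carries the host gene_id).
#' @export
count_uorf <- function(pos, ann, condition = NULL, replicate = NULL) {
  validate_positions(pos, ann)
  uo <- ann$uorfs
  if (nrow(uo) == 0) ribote_stop("count_uorf: annotation has no uORFs")
  dt <- data.table::as.data.table(pos)
  udt <- data.table::data.table(
    transcript_id = uo$transcript_id, uorf_id = uo$uorf_id,
    host_gene = uo$gene_id, ustart = uo$start, ulen = uo$length)
  dt <- merge(dt, udt, by = "transcript_id", allow.cartesian = TRUE)
  dt <- dt[position >= ustart & position < ustart + ulen]
  agg <- dt[, list(count = sum(count)), by = c("uorf_id", "sample_id")]
  data.table::setnames(agg, "uorf_id", "gene_id")
  samples <- sort(unique(as.character(pos$sample_id)))
  se <- build_count_se(agg, uo$uorf_id, samples, "RP", condition, replicate)
  SummarizedExperiment::rowData(se)$gene_id <-
    uo$gene_id[match(rownames(se), uo$uorf_id)]
  se
}

build_count_se <- function(agg, genes, samples, assay_type,
                           condition = NULL, replicate = NULL) {
  mat <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  agg <- agg[agg$gene_id %in% genes, ]
  mat[cbind(match(agg$gene_id, genes), match(agg$sample_id, samples))] <-
    as.integer(agg$count)
  if (is.null(condition) || is.null(replicate)) {
    parsed <- regmatches(samples, regexec("^(WT|MUT)_([0-9]+)$", samples))
    if (any(lengths(parsed) != 3)) {
      ribote_stop("sample ids are not of the form WT_<i>/MUT_<i>; pass condition/replicate explicitly")
    }
    condition <- vapply(parsed, `[`, character(1), 2)
    replicate <- as.integer(vapply(parsed, `[`, character(1), 3))
  }
  # canonical column order: WT before MUT, replicates ascending
  o <- order(match(condition, c("WT", "MUT")), replicate)
  count_matrix(mat[, o, drop = FALSE], assay_type, condition[o], replicate[o])
}

#' Filter genes by total mRNA reads across a strain pair
#'
#' Excludes genes with fewer than `threshold` (default 128) total mRNA reads
#' summed over the four libraries of a strain pair (two replicates each of
#' WT and mutant). "Fewer than 128" excludes; a total of exactly 128 is
#' kept. By default the input must contain exactly four RNA samples, two per
#' condition; set `require_four = FALSE` to apply the same total-count rule
#' to other layouts.
#'
#' @param rna an RNA [count_matrix()] SummarizedExperiment.
#' @param threshold minimum total mRNA reads (default 128).
#' @param require_four enforce the 2 WT + 2 MUT sample layout (default TRUE).
#' @return character vector of kept gene ids.
#' @export
filter_low_expression <- function(rna, threshold = 128, require_four = TRUE) {
  cond <- cm_condition(rna)
  if (require_four) {
    if (ncol(rna) != 4L || sum(cond == "WT") != 2L || sum(cond == "MUT") != 2L) {
      ribote_stop(paste(
        "filter_low_expression: expected exactly four RNA samples",
        "(2 WT + 2 MUT of one strain pair); pass require_four = FALSE to",
        "override"), class = "ribote_config_error")
    }
  }
  totals <- rowSums(cm_counts(rna))
  names(totals)[totals >= threshold]
}
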