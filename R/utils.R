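# Internal helpers shared across modules.

.datatable.aware <- TRUE

# data.table column names used with non-standard evaluation
utils::globalVariables(c(
  "codon", "win_hi", "position", "cds_start", "cds_codons", "count",
  "ustart", "ulen", "sample_id", "transcript_id", "gene_id"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing errors in ribote carry a class so callers (and the CLI)
#' can distinguish input errors from internal ones.
#' @noRd
ribote_stop <- function(msg, class = "ribote_input_error", ...) {
  stop(structure(
    class = c(class, "ribote_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Validate that a data frame has mandatory columns
#' @noRd
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    ribote_stop(sprintf(
      "%s: missing mandatory column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "ribote_schema_error")
  }
  invisible(df)
}

#' Geometric mean of strictly positive values
#' @noRd
geomean <- function(x) exp(mean(log(x)))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Build a CountMatrix (SummarizedExperiment) from a counts matrix
#'
#' The canonical count container in ribote: genes x samples integer counts
#' with colData columns `assay_type` (RP or RNA), `condition` (WT or MUT)
#' and `replicate`.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param assay_type "RP" or "RNA".
#' @param condition character vector per column, values in WT/MUT.
#' @param replicate integer vector per column.
#' @param size_factor_true optional planted size factors (simulation only).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `counts`.
#' @export
count_matrix <- function(counts, assay_type, condition, replicate,
                         size_factor_true = NULL) {
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) {
    ribote_stop("count_matrix: negative counts are not allowed")
  }
  assay_type <- match.arg(assay_type, c("RP", "RNA"))
  condition <- match.arg(condition, c("WT", "MUT"), several.ok = TRUE)
  if (length(condition) != ncol(counts) || length(replicate) != ncol(counts)) {
    ribote_stop("count_matrix: metadata length must match number of columns")
  }
  cd <- S4Vectors::DataFrame(
    assay_type = rep(assay_type, ncol(counts)),
    condition = condition,
    replicate = as.integer(replicate),
    row.names = colnames(counts)
  )
  if (!is.null(size_factor_true)) cd$size_factor_true <- size_factor_true
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd
  )
}

#' Extract the counts assay as a plain matrix
#' @noRd
cm_counts <- function(se) {
  as.matrix(SummarizedExperiment::assay(se, "counts"))
}

cm_condition <- function(se) {
  as.character(SummarizedExperiment::colData(se)$condition)
}

#' Deterministic 32-bit sub-seed from a base seed and a stream label
#'
#' Keeps every stage's RNG stream independent while derived from one user
#' seed; result always fits a 32-bit signed integer.
#' @noRd
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}
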