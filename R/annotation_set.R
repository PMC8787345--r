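#' Construct and validate an annotation set
#'
#' The internal coordinate convention throughout ribote is 0-based, half-open,
#' in the transcript frame (5' end = position 0). `cds_start` equals the TL
#' length; uORFs must lie entirely within the TL.
#'
#' @param transcripts data.frame with columns gene_id, transcript_id,
#'   tx_length, tl_length, cds_start, cds_length.
#' @param uorfs data.frame with columns gene_id, transcript_id, uorf_id,
#'   start, length, start_codon (may be empty).
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(transcripts, uorfs = empty_uorf_frame()) {
  check_columns(transcripts, c("gene_id", "transcript_id", "tx_length",
                               "tl_length", "cds_start", "cds_length"),
                "annotation_set transcripts")
  check_columns(uorfs, c("gene_id", "transcript_id", "uorf_id", "start",
                         "length", "start_codon"), "annotation_set uorfs")
  tr <- transcripts
  if (any(tr$cds_length %% 3L != 0L)) {
    bad <- tr$transcript_id[tr$cds_length %% 3L != 0L]
    ribote_stop(sprintf(
      "annotation_set: CDS length not divisible by 3 for: %s",
      paste(head(bad, 5), collapse = ", ")))
  }
  if (any(tr$cds_length < 3L)) {
    ribote_stop("annotation_set: CDS length must be >= 3 nt")
  }
  if (any(tr$cds_start != tr$tl_length)) {
    ribote_stop("annotation_set: cds_start must equal tl_length (transcript frame)")
  }
  if (any(tr$cds_start + tr$cds_length > tr$tx_length)) {
    ribote_stop("annotation_set: CDS extends past transcript end")
  }
  if (nrow(uorfs) > 0) {
    tl <- tr$tl_length[match(uorfs$transcript_id, tr$transcript_id)]
    if (anyNA(tl)) {
      ribote_stop("annotation_set: uORF references unknown transcript")
    }
    if (any(uorfs$length < 3L) || any(uorfs$length %% 3L != 0L)) {
      ribote_stop("annotation_set: uORF lengths must be positive multiples of 3")
    }
    if (any(uorfs$start < 0L) || any(uorfs$start + uorfs$length > tl)) {
      ribote_stop("annotation_set: uORFs must lie entirely within the transcript leader")
    }
  }
  structure(list(transcripts = tr, uorfs = uorfs), class = "annotation_set")
}

empty_uorf_frame <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             uorf_id = character(), start = integer(), length = integer(),
             start_codon = character(), stringsAsFactors = FALSE)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d transcripts, %d uORFs\n",
              nrow(x$transcripts), nrow(x$uorfs)))
  invisible(x)
}
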