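# FASTA sequence and bedGraph PARS-track I/O.

#' Write transcript sequences to FASTA
#' @param seqs a [Biostrings::DNAStringSet] named by transcript id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read transcript sequences from FASTA
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_sequences <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write per-nt PARS tracks to bedGraph
#'
#' Tracks are emitted as 0-based half-open bedGraph intervals on transcript
#' "chromosomes", with runs of equal values merged; `NA` positions are
#' omitted (bedGraph has no missing-value representation, so absent
#' positions read back as missing).
#'
#' @param tracks named list of per-nt numeric vectors (class `pars_tracks`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pars <- function(tracks, path) {
  lens <- lengths(tracks)
  tx <- rep(names(tracks), lens)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  v <- unlist(tracks, use.names = FALSE)
  keep <- !is.na(v)
  if (!any(keep)) ribote_stop("write_pars: all values missing")
  gr <- GenomicRanges::GRanges(
    seqnames = tx[keep],
    ranges = IRanges::IRanges(start = pos[keep], width = 1L),
    score = v[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a PARS bedGraph into per-nt tracks
#'
#' Expands bedGraph intervals to per-nucleotide score vectors whose lengths
#' come from the annotation; positions not covered by any interval are `NA`.
#'
#' @param path bedGraph path.
#' @param ann an `annotation_set` supplying transcript lengths.
#' @return named list of numeric vectors (class `pars_tracks`), one per
#'   annotated transcript.
#' @export
read_pars <- function(path, ann) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tr <- ann$transcripts
  w <- GenomicRanges::width(gr)
  if (all(w == 1L)) {  # fast path: single-nt intervals need no expansion
    tx <- as.character(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    val <- gr$score
  } else {
    tx <- rep(as.character(GenomicRanges::seqnames(gr)), w)
    st <- GenomicRanges::start(gr)
    pos <- sequence(w, from = st)
    val <- rep(gr$score, w)
  }
  tracks <- lapply(setNames(tr$tx_length, tr$transcript_id),
                   function(len) rep(NA_real_, len))
  idx_by_tx <- split(seq_along(pos), tx)
  for (t in names(idx_by_tx)) {
    if (!t %in% names(tracks)) {
      ribote_stop(sprintf("read_pars: unknown transcript in bedGraph: %s", t))
    }
    i <- idx_by_tx[[t]]
    if (max(pos[i]) > length(tracks[[t]])) {
      ribote_stop(sprintf("read_pars: interval beyond transcript end for %s", t))
    }
    tracks[[t]][pos[i]] <- val[i]
  }
  structure(tracks, class = "pars_tracks")
}
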