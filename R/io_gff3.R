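# GFF3 I/O for transcript-frame annotation.
#
# Files carry the standard "##gff-version 3" header plus a convention pragma
# "#!coordinates transcript" declaring that seqids are transcript identifiers
# and coordinates are 1-based inclusive positions on the transcript (per the
# GFF3 standard), converted to 0-based half-open internally. rtracklayer is
# deliberately not used here: these files need line-number error reporting,
# CDS-length validation with per-record rejection, and a byte-stable
# write/read round trip, none of which its genomic GFF3 importer provides.

GFF_COORD_PRAGMA <- "#!coordinates transcript"

#' Write an annotation set to GFF3
#'
#' Emits transcript, CDS and uORF features in 1-based inclusive coordinates,
#' ordered by transcript then feature type, so that write -> read -> write is
#' byte-identical.
#'
#' @param ann an `annotation_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  tr <- ann$transcripts[order(ann$transcripts$transcript_id), , drop = FALSE]
  lines <- c("##gff-version 3", GFF_COORD_PRAGMA)
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    lines <- c(lines,
      gff_line(t$transcript_id, "transcript", 0L, t$tx_length, ".",
               sprintf("ID=%s;gene_id=%s", t$transcript_id, t$gene_id)),
      gff_line(t$transcript_id, "CDS", t$cds_start,
               t$cds_start + t$cds_length, "0",
               sprintf("ID=%s.cds;Parent=%s", t$transcript_id, t$transcript_id))
    )
    u <- ann$uorfs[ann$uorfs$transcript_id == t$transcript_id, , drop = FALSE]
    if (nrow(u) > 0) {
      u <- u[order(u$uorf_id), , drop = FALSE]
      for (j in seq_len(nrow(u))) {
        lines <- c(lines, gff_line(
          t$transcript_id, "uORF", u$start[j], u$start[j] + u$length[j], ".",
          sprintf("ID=%s;Parent=%s;start_codon=%s",
                  u$uorf_id[j], t$transcript_id, u$start_codon[j])))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# start0/end0 are 0-based half-open; GFF3 is 1-based inclusive
gff_line <- function(seqid, type, start0, end0, phase, attrs) {
  paste(seqid, "ribote", type, start0 + 1L, end0, ".", "+", phase, attrs,
        sep = "\t")
}

#' Read a transcript-frame GFF3 annotation
#'
#' Parses transcript/CDS/uORF features, converts 1-based inclusive intervals
#' to the internal 0-based half-open transcript frame, and validates all
#' `annotation_set` invariants. Malformed lines raise an error naming the
#' line number; CDS records whose length is not a multiple of 3 cause their
#' transcript to be rejected with a warning.
#'
#' @param path GFF3 file path.
#' @return an `annotation_set`.
#' @export
read_annotation <- function(path) {
  raw <- readLines(path)
  body_idx <- which(!startsWith(raw, "#") & nzchar(raw))
  if (length(body_idx) == 0L) ribote_stop("read_annotation: no feature lines")
  fields <- strsplit(raw[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- body_idx[which(nf != 9L)[1]]
    ribote_stop(sprintf(
      "read_annotation: malformed GFF3 line %d (expected 9 tab-separated fields, found %d)",
      bad, nf[which(nf != 9L)[1]]))
  }
  m <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- body_idx[which(is.na(start1) | is.na(end1))[1]]
    ribote_stop(sprintf(
      "read_annotation: malformed GFF3 line %d (non-numeric coordinates)", bad))
  }
  feat <- data.frame(
    seqid = m[, 1], type = m[, 3],
    start0 = start1 - 1L, end0 = end1,   # to 0-based half-open
    attrs = m[, 9], line = body_idx, stringsAsFactors = FALSE
  )
  if (any(feat$start0 < 0 | feat$end0 <= feat$start0)) {
    bad <- feat$line[which(feat$start0 < 0 | feat$end0 <= feat$start0)[1]]
    ribote_stop(sprintf(
      "read_annotation: malformed GFF3 line %d (empty or negative interval)", bad))
  }

  tx <- feat[feat$type == "transcript", , drop = FALSE]
  cds <- feat[feat$type == "CDS", , drop = FALSE]
  uo <- feat[feat$type == "uORF", , drop = FALSE]

  cds_len <- cds$end0 - cds$start0
  bad_cds <- cds_len %% 3L != 0L
  if (any(bad_cds)) {
    warning(sprintf(
      "read_annotation: rejected %d CDS record(s) with length not divisible by 3 (transcripts: %s)",
      sum(bad_cds), paste(head(cds$seqid[bad_cds], 5), collapse = ", ")),
      call. = FALSE)
    drop_tx <- unique(cds$seqid[bad_cds])
    tx <- tx[!tx$seqid %in% drop_tx, , drop = FALSE]
    cds <- cds[!bad_cds, , drop = FALSE]
    uo <- uo[!uo$seqid %in% drop_tx, , drop = FALSE]
  }

  ci <- match(tx$seqid, cds$seqid)
  if (anyNA(ci)) {
    ribote_stop(sprintf("read_annotation: transcript(s) without CDS: %s",
                        paste(head(tx$seqid[is.na(ci)], 5), collapse = ", ")))
  }
  transcripts <- data.frame(
    gene_id = attr_value(tx$attrs, "gene_id"),
    transcript_id = tx$seqid,
    tx_length = tx$end0,
    tl_length = cds$start0[ci],
    cds_start = cds$start0[ci],
    cds_length = cds$end0[ci] - cds$start0[ci],
    stringsAsFactors = FALSE
  )
  uorfs <- if (nrow(uo) > 0) {
    data.frame(
      gene_id = transcripts$gene_id[match(uo$seqid, transcripts$transcript_id)],
      transcript_id = uo$seqid,
      uorf_id = attr_value(uo$attrs, "ID"),
      start = uo$start0,
      length = uo$end0 - uo$start0,
      start_codon = attr_value(uo$attrs, "start_codon"),
      stringsAsFactors = FALSE
    )
  } else {
    empty_uorf_frame()
  }
  annotation_set(transcripts, uorfs)
}

attr_value <- function(attrs, key) {
  pat <- paste0("(^|;)", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(g) if (length(g) >= 3) g[3] else NA_character_,
         character(1))
}
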