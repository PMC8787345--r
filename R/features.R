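# Transcript-leader feature scoring: PARS window statistics, Kozak context
# PWM scoring, sequence-logo matrices, uORF cap distances, and the assembled
# per-gene feature table.

#' PARS window statistics over the transcript leader
#'
#' Computes one of five secondary-structure statistics from a per-nucleotide
#' PARS track (higher = more double-stranded), in the 0-based half-open
#' transcript frame:
#'
#' * `utr_all`: mean over the whole TL `[0, tl)`;
#' * `first30`: mean over the first 30 nt of the TL `[0, 30)`;
#' * `start30`: mean over the 30 nt centred on the start codon,
#'   `[cds_start - 15, cds_start + 15)`;
#' * `plus30`: mean over the 30 nt downstream of the start30 window,
#'   `[cds_start + 15, cds_start + 45)`;
#' * `max30`: maximum over all 30-nt windows fully contained in the TL of
#'   the window mean (1-nt step).
#'
#' Windows not fully contained in the transcript (or, for `first30`/`max30`,
#' in the TL) are missing; a window containing any missing PARS value yields
#' a missing statistic (for `max30`, windows with missing data are excluded
#' and the statistic is missing only if no complete window exists).
#'
#' @param track per-nt numeric PARS vector, length = transcript length.
#' @param tl_length TL length (nt).
#' @param cds_start 0-based CDS start offset (= `tl_length`).
#' @param window statistic name (see above).
#' @param width window width in nt (default 30).
#' @return a single numeric value or `NA`.
#' @export
pars_window_stat <- function(track, tl_length, cds_start = tl_length,
                             window = c("utr_all", "first30", "start30",
                                        "plus30", "max30"),
                             width = 30L) {
  window <- match.arg(window)
  n <- length(track)
  win_mean <- function(from, to, bound = n) {  # [from, to) 0-based
    if (from < 0 || to > bound || to <= from) return(NA_real_)
    v <- track[(from + 1):to]
    if (anyNA(v)) NA_real_ else mean(v)
  }
  switch(window,
    utr_all = win_mean(0, tl_length, bound = tl_length),
    first30 = win_mean(0, width, bound = tl_length),
    start30 = win_mean(cds_start - width %/% 2, cds_start + width %/% 2),
    plus30 = win_mean(cds_start + width %/% 2, cds_start + width %/% 2 + width),
    max30 = {
      if (tl_length < width) return(NA_real_)
      means <- vapply(0:(tl_length - width), function(i) {
        win_mean(i, i + width, bound = tl_length)
      }, numeric(1))
      if (all(is.na(means))) NA_real_ else max(means, na.rm = TRUE)
    }
  )
}

#' Extract -6..+4 start-codon context windows
#'
#' Returns, per transcript, the 10-nt sequence covering nt -6..-1 upstream of
#' the AUG, the AUG itself (+1..+3), and nt +4; `NA` when the TL is shorter
#' than 6 nt or the transcript ends before +4.
#'
#' @param seqs [Biostrings::DNAStringSet] named by transcript id.
#' @param ann an `annotation_set`.
#' @return named character vector of 10-mers (or `NA`).
#' @export
context_windows <- function(seqs, ann) {
  tr <- ann$transcripts
  out <- setNames(rep(NA_character_, nrow(tr)), tr$transcript_id)
  for (i in seq_len(nrow(tr))) {
    tx <- tr$transcript_id[i]
    if (!tx %in% names(seqs)) {
      ribote_stop(sprintf("context_windows: no sequence for %s", tx))
    }
    s <- seqs[[tx]]
    if (length(s) != tr$tx_length[i]) {
      ribote_stop(sprintf(
        "context_windows: sequence/annotation length mismatch for %s (%d vs %d)",
        tx, length(s), tr$tx_length[i]))
    }
    cs <- tr$cds_start[i]
    if (cs >= 6 && cs + 4 <= length(s)) {
      out[tx] <- as.character(Biostrings::subseq(s, cs - 5, cs + 4))
    }
  }
  out
}

#' Build a Kozak-context position weight matrix
#'
#' From a set of 10-nt context windows (positions -6..-1, AUG, +4), builds a
#' position probability matrix with pseudocount 1 and converts it to log2
#' odds against the pooled background base composition of the inputs'
#' -6..-1 positions. The AUG core columns are forced to zero log-odds so the
#' invariant start codon contributes nothing to scores. Windows whose
#' +1..+3 core is not AUG are rejected with a warning.
#'
#' @param windows character vector of 10-mers (NAs dropped).
#' @return object of class `context_pwm`: list(log_odds 4 x 10 matrix,
#'   probs, background, n).
#' @export
build_context_pwm <- function(windows) {
  windows <- windows[!is.na(windows)]
  if (length(windows) == 0) ribote_stop("build_context_pwm: no context windows")
  if (any(nchar(windows) != 10L)) {
    ribote_stop("build_context_pwm: windows must be exactly 10 nt")
  }
  core_ok <- substr(windows, 7, 9) == "ATG"
  if (any(!core_ok)) {
    warning(sprintf("build_context_pwm: rejected %d window(s) without an AUG core",
                    sum(!core_ok)), call. = FALSE)
    windows <- windows[core_ok]
  }
  if (length(windows) == 0) ribote_stop("build_context_pwm: no valid windows")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
                byrow = TRUE)
  counts <- apply(mat, 2, function(col) table(factor(col, levels = bases)))
  probs <- sweep(counts + 1, 2, colSums(counts) + 4, `/`)  # pseudocount 1
  up <- as.vector(mat[, 1:6])
  bg_counts <- table(factor(up, levels = bases))
  background <- (bg_counts + 1) / (sum(bg_counts) + 4)
  log_odds <- log2(probs / as.numeric(background))
  log_odds[, 7:9] <- 0
  dimnames(log_odds) <- list(bases, c(paste0("m", 6:1), "p1", "p2", "p3", "p4"))
  structure(list(log_odds = log_odds, probs = probs,
                 background = as.numeric(background), n = length(windows)),
            class = "context_pwm")
}

#' Score a start-codon context against a PWM
#'
#' Sum of per-position log2-odds over nt -6..-1 and +4 (the AUG core
#' contributes 0 by construction). `NA` windows score `NA`.
#'
#' @param window a 10-nt context window (or vector thereof).
#' @param pwm a `context_pwm` from [build_context_pwm()].
#' @return numeric score(s).
#' @export
context_score <- function(window, pwm) {
  stopifnot(inherits(pwm, "context_pwm"))
  vapply(window, function(w) {
    if (is.na(w)) return(NA_real_)
    if (nchar(w) != 10L) ribote_stop("context_score: window must be 10 nt")
    chars <- strsplit(w, "")[[1]]
    idx <- match(chars, rownames(pwm$log_odds))
    if (anyNA(idx)) return(NA_real_)
    sum(pwm$log_odds[cbind(idx, seq_len(10))])
  }, numeric(1), USE.NAMES = !is.null(names(window)))
}

#' Sequence-logo matrix for aligned context windows
#'
#' Per-position base frequencies and information content
#' `IC_j = 2 + sum_b p_bj log2 p_bj` (bits, no small-sample correction),
#' suitable for logo plotting.
#'
#' @param windows character vector of aligned 10-mers (NAs dropped).
#' @return list with `freq` (4 x 10) and `ic` (length 10, bits in \[0, 2\]).
#' @export
sequence_logo_matrix <- function(windows) {
  windows <- windows[!is.na(windows)]
  if (length(windows) == 0) ribote_stop("sequence_logo_matrix: empty window set")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
                byrow = TRUE)
  freq <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = bases))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- bases
  ic <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  list(freq = freq, ic = ic)
}

#' uORF distances from the transcript 5' cap
#'
#' @param ann an `annotation_set`.
#' @return data.frame: gene_id, uorf_id, cap_distance (nt, = 0-based uORF
#'   start offset), in annotation order.
#' @export
uorf_cap_distance <- function(ann) {
  u <- ann$uorfs
  data.frame(gene_id = u$gene_id, uorf_id = u$uorf_id,
             cap_distance = u$start, stringsAsFactors = FALSE)
}

#' Assemble the per-gene feature table
#'
#' Combines 5'-UTR length from the dominant-isoform rule (missing where no
#' isoform dominates), CDS/transcript lengths, the five PARS window
#' statistics on the modelled transcript, the Kozak context score (PWM built
#' from the analysis universe itself unless one is supplied), and the
#' closed-loop group.
#'
#' @param ann an `annotation_set`.
#' @param seqs transcript sequences ([Biostrings::DNAStringSet]).
#' @param pars `pars_tracks` (named list of per-nt scores).
#' @param isoforms isoform table (see [read_isoforms()]); NULL uses the
#'   modelled TL length for every gene.
#' @param closed_loop data.frame(gene_id, group) or NULL.
#' @param pwm optional pre-built `context_pwm`.
#' @return data.frame of class `feature_table`, one row per gene.
#' @export
build_feature_table <- function(ann, seqs, pars, isoforms = NULL,
                                closed_loop = NULL, pwm = NULL) {
  tr <- ann$transcripts
  windows <- context_windows(seqs, ann)
  if (is.null(pwm)) pwm <- build_context_pwm(windows)
  dom_tl <- if (is.null(isoforms)) {
    setNames(as.numeric(tr$tl_length), tr$gene_id)
  } else {
    select_dominant_isoform(isoforms)
  }
  stat_names <- c("utr_all", "first30", "start30", "plus30", "max30")
  stats <- t(vapply(seq_len(nrow(tr)), function(i) {
    track <- pars[[tr$transcript_id[i]]]
    if (is.null(track)) return(rep(NA_real_, 5))
    vapply(stat_names, function(w) {
      pars_window_stat(track, tr$tl_length[i], tr$cds_start[i], w)
    }, numeric(1))
  }, numeric(5)))
  colnames(stats) <- paste0("pars_", stat_names)
  ft <- data.frame(
    gene_id = tr$gene_id,
    tl_length = as.numeric(dom_tl[tr$gene_id]),
    cds_length = tr$cds_length,
    transcript_length = tr$tx_length,
    stats,
    context_score = as.numeric(context_score(windows[tr$transcript_id], pwm)),
    closed_loop_group = if (is.null(closed_loop)) NA_integer_ else
      closed_loop$group[match(tr$gene_id, closed_loop$gene_id)],
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(ft)[names(ft) == "pars_utr_all"] <- "pars_mean_utr"
  class(ft) <- c("feature_table", "data.frame")
  ft
}
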