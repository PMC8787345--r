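#' Generate a synthetic transcriptome with known ground truth
#'
#' Produces annotation, transcript sequences, per-nt PARS tracks, an isoform
#' table and a truth table emulating the statistical structure the downstream
#' analysis assumes: variable transcript-leader (TL) lengths, isoform mixtures
#' with a controlled fraction of genes passing the 40%/2x dominance rule,
#' Kozak contexts of tunable strength around the CDS AUG, uORFs within the TL,
#' plantable 30-nt structured PARS windows, and per-gene true log2 dTE_rel
#' values linked to TL length, Max30 PARS and context strength through the
#' configured effect model.
#'
#' All randomness derives from `config$seed`; identical configurations yield
#' byte-identical outputs.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `ribote_simdata` with elements `annotation`
#'   (an `annotation_set`), `sequences` ([Biostrings::DNAStringSet]), `pars`
#'   (named list of per-nt numeric tracks), `isoforms` (data.frame:
#'   gene_id, isoform_id, tl_length, relative_abundance), `truth`
#'   (data.frame of planted values, one row per gene), `closed_loop`
#'   (data.frame: gene_id, group) and `config`.
#' @seealso [generate_counts()] for the paired count stage.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 10) {
    ribote_stop(paste(
      "generate_transcriptome: n_genes must be >= 10;",
      "smaller simulations cannot support the downstream dispersion trend",
      "and FDR statistics."
    ))
  }
  set.seed(derive_seed(config$seed, "transcriptome"))
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  transcript_id <- paste0(gene_id, "_t1")

  tl <- draw_lengths(n, config$tl_length_dist)
  cds_codons <- draw_lengths(n, config$cds_length_dist)
  cds_length <- 3L * cds_codons
  utr3 <- draw_lengths(n, c(config$utr3_length_dist, list(min = 20)))
  tx_length <- tl + cds_length + utr3

  context_strength <- rbeta(n, config$context_strength_dist$shape1,
                            config$context_strength_dist$shape2)

  uorfs <- sample_uorfs(gene_id, transcript_id, tl, config$uorf_rate)

  seqs <- vapply(seq_len(n), function(i) {
    make_tx_sequence(
      tl = tl[i], cds_length = cds_length[i], utr3 = utr3[i],
      strength = context_strength[i],
      uorfs = uorfs[uorfs$transcript_id == transcript_id[i], , drop = FALSE]
    )
  }, character(1))
  sequences <- Biostrings::DNAStringSet(setNames(seqs, transcript_id))

  pars <- make_pars_tracks(transcript_id, tl, tx_length, config$pars_model)
  max30_true <- vapply(seq_len(n), function(i) {
    sliding_window_max(pars$tracks[[i]], tl[i], config$pars_model$window)
  }, numeric(1))

  isoforms <- make_isoform_table(gene_id, transcript_id, tl,
                                 config$frac_dominant)
  dominant <- gene_id %in%
    isoforms$gene_id[isoforms$dominant_by_construction &
                       !duplicated(isoforms$gene_id)]

  closed_loop <- data.frame(
    gene_id = gene_id,
    group = sample(1:4, n, replace = TRUE, prob = c(0.25, 0.25, 0.3, 0.2))
  )

  # Planted expression and dispersion model
  true_mean_rna <- rlnorm(n, config$mean_expression_dist$meanlog,
                          config$mean_expression_dist$sdlog)
  disp_trend <- function(mu) {
    config$dispersion_model$asymptotic + config$dispersion_model$extra_poisson / mu
  }
  jit <- config$dispersion_model$sdlog_jitter %||% 0
  dispersion_rna <- disp_trend(true_mean_rna) * rlnorm(n, 0, jit)
  dispersion_rp <- disp_trend(true_mean_rna * config$rp_depth_factor) *
    rlnorm(n, 0, jit)
  true_te_wt <- rlnorm(n, config$te_wt_dist$meanlog, config$te_wt_dist$sdlog)

  # Effect model: true log2 dTE_rel for non-null genes is a linear function
  # of centred planted features plus Gaussian noise.
  em <- config$effect_model
  max30_feat <- ifelse(is.na(max30_true), mean(max30_true, na.rm = TRUE),
                       max30_true)
  if (all(is.na(max30_true))) max30_feat <- rep(0, n)
  lin <- em$intercept +
    em$utr_length * (tl - mean(tl)) +
    em$max30 * (max30_feat - mean(max30_feat)) +
    em$context_score * (context_strength - mean(context_strength)) +
    rnorm(n, 0, em$sd)
  n_null <- round(config$frac_null * n)
  null_idx <- sample.int(n, n_null)
  true_log2_dte <- lin
  true_log2_dte[null_idx] <- 0

  truth <- data.frame(
    gene_id = gene_id, transcript_id = transcript_id,
    tl_length = tl, cds_length = cds_length, utr3_length = utr3,
    tx_length = tx_length,
    n_uorfs = as.integer(table(factor(uorfs$gene_id, levels = gene_id))),
    context_strength = context_strength,
    pars_max30_true = max30_true,
    structured_window = pars$structured,
    closed_loop_group = closed_loop$group,
    dominant = dominant,
    is_null = seq_len(n) %in% null_idx,
    true_log2_dte = true_log2_dte,
    true_mean_rna = true_mean_rna,
    true_te_wt = true_te_wt,
    dispersion_rp = dispersion_rp,
    dispersion_rna = dispersion_rna,
    stringsAsFactors = FALSE
  )
  class(truth) <- c("truth_table", "data.frame")

  ann <- annotation_set(
    transcripts = data.frame(
      gene_id = gene_id, transcript_id = transcript_id,
      tx_length = tx_length, tl_length = tl,
      cds_start = tl, cds_length = cds_length,
      stringsAsFactors = FALSE
    ),
    uorfs = uorfs
  )

  structure(list(
    annotation = ann, sequences = sequences,
    pars = structure(pars$tracks, class = "pars_tracks"),
    isoforms = isoforms[, c("gene_id", "isoform_id", "tl_length",
                            "relative_abundance")],
    truth = truth, closed_loop = closed_loop, config = config
  ), class = "ribote_simdata")
}

draw_lengths <- function(n, dist) {
  x <- round(rlnorm(n, dist$meanlog, dist$sdlog))
  if (!is.null(dist$min)) x <- pmax(x, dist$min)
  if (!is.null(dist$max)) x <- pmin(x, dist$max)
  as.integer(x)
}

# Max over all fully-contained w-nt window means in [0, tl); NA if tl < w or
# no window has complete data.
sliding_window_max <- function(track, tl, w = 30L) {
  if (tl < w) return(NA_real_)
  cs <- cumsum(c(0, ifelse(is.na(track[seq_len(tl)]), NA, track[seq_len(tl)])))
  means <- (cs[(w + 1):(tl + 1)] - cs[1:(tl - w + 1)]) / w
  if (anyNA(track[seq_len(tl)])) {
    # recompute per window honestly when missing values are present
    means <- vapply(0:(tl - w), function(i) {
      win <- track[(i + 1):(i + w)]
      if (anyNA(win)) NA_real_ else mean(win)
    }, numeric(1))
  }
  if (all(is.na(means))) NA_real_ else max(means, na.rm = TRUE)
}

sample_uorfs <- function(gene_id, transcript_id, tl, rate) {
  out <- list()
  starts <- c("ATG", "TTG", "GTG", "CTG", "ACG")
  for (i in seq_along(gene_id)) {
    k <- rpois(1, rate)
    if (k == 0 || tl[i] < 12) next
    rows <- list()
    for (j in seq_len(k)) {
      max_codons <- min(8L, floor(tl[i] / 3) - 1L)
      if (max_codons < 2) next
      len <- 3L * sample(2:max_codons, 1)
      if (len > tl[i]) next
      start <- sample(0:(tl[i] - len), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id[i], transcript_id = transcript_id[i],
        uorf_id = sprintf("%s_uORF%d", transcript_id[i], j),
        start = start, length = len,
        start_codon = sample(starts, 1, prob = c(0.6, 0.1, 0.1, 0.1, 0.1)),
        stringsAsFactors = FALSE
      )
    }
    if (length(rows)) out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      uorf_id = character(), start = integer(),
                      length = integer(), start_codon = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

KOZAK_CONSENSUS_UP <- c("A", "A", "A", "A", "A", "A")  # nt -6..-1
KOZAK_CONSENSUS_P4 <- "G"                              # nt +4
YEAST_BASE_FREQS <- c(A = 0.31, C = 0.19, G = 0.19, T = 0.31)

make_tx_sequence <- function(tl, cds_length, utr3, strength, uorfs) {
  len <- tl + cds_length + utr3
  s <- sample(names(YEAST_BASE_FREQS), len, replace = TRUE,
              prob = YEAST_BASE_FREQS)
  # uORF start/stop codons first so the Kozak context written below wins any
  # overlap at the TL 3' end
  if (nrow(uorfs) > 0) {
    for (j in seq_len(nrow(uorfs))) {
      st <- uorfs$start[j]
      s[(st + 1):(st + 3)] <- strsplit(uorfs$start_codon[j], "")[[1]]
      stop_at <- st + uorfs$length[j] - 3L
      s[(stop_at + 1):(stop_at + 3)] <- strsplit(
        sample(c("TAA", "TAG", "TGA"), 1), "")[[1]]
    }
  }
  # Kozak context: each of nt -6..-1 and +4 matches the consensus with
  # probability 0.25 + 0.75 * strength, otherwise is a random base
  p_cons <- 0.25 + 0.75 * strength
  if (tl >= 6) {
    for (k in 1:6) {
      pos <- tl - 6 + k
      s[pos] <- if (runif(1) < p_cons) KOZAK_CONSENSUS_UP[k] else
        sample(names(YEAST_BASE_FREQS), 1)
    }
  }
  s[(tl + 1):(tl + 3)] <- c("A", "T", "G")
  s[tl + 4] <- if (runif(1) < p_cons) KOZAK_CONSENSUS_P4 else
    sample(names(YEAST_BASE_FREQS), 1)
  # terminal stop codon of the main CDS
  stop_at <- tl + cds_length - 3L
  s[(stop_at + 1):(stop_at + 3)] <- strsplit(
    sample(c("TAA", "TAG", "TGA"), 1), "")[[1]]
  paste(s, collapse = "")
}

make_pars_tracks <- function(transcript_id, tl, tx_length, pm) {
  n <- length(transcript_id)
  structured <- logical(n)
  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- rnorm(tx_length[i], pm$baseline_mean, pm$noise_sd)
    if (tl[i] >= pm$window && runif(1) < pm$structured_rate) {
      w0 <- sample(0:(tl[i] - pm$window), 1)
      tr[(w0 + 1):(w0 + pm$window)] <- tr[(w0 + 1):(w0 + pm$window)] +
        pm$structured_effect
      structured[i] <- TRUE
    }
    if ((pm$missing_rate %||% 0) > 0) {
      tr[runif(tx_length[i]) < pm$missing_rate] <- NA_real_
    }
    tracks[[i]] <- tr
  }
  names(tracks) <- transcript_id
  list(tracks = tracks, structured = structured)
}

# Dominant genes: top isoform abundance in [0.7, 0.95] with <= 2 minors, so
# top >= 0.40 and top >= 2 x every minor holds by construction.
# Non-dominant genes: 3 isoforms with top in [0.42, 0.48] and second
# > 0.6 x top, violating the 2x clause whichever minor ranks second.
make_isoform_table <- function(gene_id, transcript_id, tl, frac_dominant) {
  n <- length(gene_id)
  n_dom <- round(frac_dominant * n)
  dom <- seq_len(n) %in% sample.int(n, n_dom)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (dom[i]) {
      k <- sample(0:2, 1)
      if (k == 0) {
        ab <- 1
      } else {
        a1 <- runif(1, 0.7, 0.95)
        minors <- runif(k)
        ab <- c(a1, (1 - a1) * minors / sum(minors))
      }
    } else {
      a1 <- runif(1, 0.42, 0.48)
      a2 <- runif(1, 0.6 * a1, 0.95 * a1)
      ab <- c(a1, a2, 1 - a1 - a2)
    }
    k_iso <- length(ab)
    tl_iso <- c(tl[i], pmax(5L, as.integer(round(
      tl[i] * runif(k_iso - 1, 0.5, 1.8)))))
    rows[[i]] <- data.frame(
      gene_id = gene_id[i],
      isoform_id = c(transcript_id[i],
                     if (k_iso > 1) sprintf("%s_t%d", gene_id[i], 2:k_iso)),
      tl_length = tl_iso,
      relative_abundance = ab,
      dominant_by_construction = dom[i],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Generate an external dTE table correlated with the simulated truth
#'
#' Emulates a published dTE_rel table from a different initiation-factor
#' mutant whose gene-level effects share planted structure with the simulated
#' strain at a configurable correlation (`config$external_cor`).
#'
#' @param truth truth table from [generate_transcriptome()].
#' @param config the same [sim_config()].
#' @param name label for the external dataset.
#' @return data.frame with columns gene_id, log2_dte.
#' @export
generate_external_dte <- function(truth, config, name = "external") {
  set.seed(derive_seed(config$seed, paste0("external_", name)))
  x <- truth$true_log2_dte
  sdx <- sd(x)
  rho <- config$external_cor
  if (sdx == 0) {
    y <- rnorm(length(x), 0, config$effect_model$sd)
  } else {
    z <- (x - mean(x)) / sdx
    y <- (rho * z + sqrt(1 - rho^2) * rnorm(length(x))) * sdx
  }
  data.frame(gene_id = truth$gene_id, log2_dte = y, stringsAsFactors = FALSE)
}
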