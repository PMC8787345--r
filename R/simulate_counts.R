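#' Generate paired footprint and RNA-seq counts from a simulated truth table
#'
#' RNA counts per gene and sample are drawn from a negative binomial with
#' mean `true_mean_rna * size_factor` and the gene's RNA dispersion
#' (`Var = mu + alpha mu^2`). Ribosome-protected (RP) counts are drawn as one
#' gene-level NB total per sample — mean proportional to
#' `true_mean_rna * TE * size_factor`, where TE is `true_te_wt` in WT and
#' `true_te_wt * 2^true_log2_dte` in the mutant — and then distributed
#' multinomially across CDS codons (uniformly, or with an optional
#' cycloheximide-like 5' ramp confined to the first 15 codons). Each uORF
#' receives NB occupancy proportional to its host gene's footprint mean.
#'
#' Size factors are planted per sample: log-uniform in [0.5, 2] unless
#' `config$size_factors` supplies explicit values. They are recorded in the
#' returned colData (`size_factor_true`) so normalization recovery is
#' testable.
#'
#' @param truth truth table from [generate_transcriptome()] (the full
#'   `ribote_simdata` object is also accepted).
#' @param config the same [sim_config()] used for the transcriptome.
#' @return list with `positions` (a `position_counts` data.table:
#'   transcript_id, position, sample_id, count — footprint occupancy at codon
#'   first-nt resolution, CDS and uORF), `rna` (a [count_matrix()]
#'   SummarizedExperiment of RNA counts), and `sample_info` (data.frame of
#'   sample metadata incl. planted size factors).
#' @export
generate_counts <- function(truth, config) {
  if (inherits(truth, "ribote_simdata")) {
    truth <- with_uorfs(truth$truth, truth$annotation)
  }
  stopifnot(inherits(config, "sim_config"))
  if (any(truth$true_mean_rna <= 0) || any(truth$true_te_wt <= 0)) {
    ribote_stop("generate_counts: planted means must be strictly positive")
  }
  set.seed(derive_seed(config$seed, "counts"))
  n <- nrow(truth)
  nrep <- config$n_replicates
  conditions <- rep(c("WT", "MUT"), each = nrep)
  replicates <- rep(seq_len(nrep), 2)
  sample_ids <- paste0(conditions, "_", replicates)
  nsamp <- length(sample_ids)

  sf <- planted_size_factors(config, nsamp)

  # --- RNA counts -----------------------------------------------------------
  rna <- matrix(0L, n, nsamp, dimnames = list(truth$gene_id, sample_ids))
  for (j in seq_len(nsamp)) {
    rna[, j] <- rnbinom(n, mu = truth$true_mean_rna * sf$rna[j],
                        size = 1 / truth$dispersion_rna)
  }
  rna_se <- count_matrix(rna, "RNA", conditions, replicates,
                         size_factor_true = sf$rna)

  # --- RP counts at codon resolution ---------------------------------------
  te <- outer(truth$true_te_wt, rep(1, nsamp))
  mut_cols <- conditions == "MUT"
  te[, mut_cols] <- te[, mut_cols] * 2^truth$true_log2_dte
  rp_mean <- config$rp_depth_factor * truth$true_mean_rna * te
  rp_mean <- sweep(rp_mean, 2, sf$rp, `*`)

  cds_codons <- truth$cds_length %/% 3L
  pieces <- vector("list", n * nsamp)
  k <- 0L
  for (i in seq_len(n)) {
    L <- cds_codons[i]
    w <- rep(1, L)
    pos0 <- truth$tl_length[i] + 3L * (seq_len(L) - 1L)
    for (j in seq_len(nsamp)) {
      tot <- rnbinom(1, mu = rp_mean[i, j], size = 1 / truth$dispersion_rp[i])
      if (tot == 0) next
      occ <- as.vector(rmultinom(1, tot, w))
      nz <- occ > 0L
      k <- k + 1L
      pieces[[k]] <- data.table::data.table(
        transcript_id = truth$transcript_id[i],
        position = pos0[nz], sample_id = sample_ids[j], count = occ[nz]
      )
    }
  }
  pos_dt <- data.table::rbindlist(pieces[seq_len(k)])

  # --- uORF occupancy -------------------------------------------------------
  uorfs <- attr(truth, "uorfs")
  if (is.null(uorfs)) uorfs <- data.frame()
  if (nrow(uorfs) > 0) {
    idx <- match(uorfs$gene_id, truth$gene_id)
    upieces <- list()
    for (u in seq_len(nrow(uorfs))) {
      i <- idx[u]
      ucodons <- uorfs$length[u] %/% 3L
      upos0 <- uorfs$start[u] + 3L * (seq_len(ucodons) - 1L)
      for (j in seq_len(nsamp)) {
        mu_u <- config$uorf_load * rp_mean[i, j]
        tot <- rnbinom(1, mu = mu_u, size = 1 / truth$dispersion_rp[i])
        if (tot == 0) next
        occ <- as.vector(rmultinom(1, tot, rep(1, ucodons)))
        nz <- occ > 0L
        upieces[[length(upieces) + 1L]] <- data.table::data.table(
          transcript_id = uorfs$transcript_id[u],
          position = upos0[nz], sample_id = sample_ids[j], count = occ[nz]
        )
      }
    }
    if (length(upieces)) {
      pos_dt <- data.table::rbindlist(c(list(pos_dt), upieces))
    }
  }
  # Optional cycloheximide-like 5' ramp: EXTRA occupancy over the first 15
  # codons, drawn from an independent RNG stream so that all base draws
  # (hence all counts outside the ramp region) are identical with the ramp
  # on or off. The codon-exclusion rule therefore removes the artifact
  # exactly, by construction.
  if (isTRUE(config$ramp$enabled)) {
    set.seed(derive_seed(config$seed, "ramp"))
    rpieces <- list()
    for (i in seq_len(n)) {
      L <- cds_codons[i]
      nr <- min(15L, L)
      pos0 <- truth$tl_length[i] + 3L * (seq_len(nr) - 1L)
      for (j in seq_len(nsamp)) {
        mu_extra <- rp_mean[i, j] * (config$ramp$fold - 1) * nr / L
        tot <- rnbinom(1, mu = mu_extra, size = 1 / truth$dispersion_rp[i])
        if (tot == 0) next
        occ <- as.vector(rmultinom(1, tot, rep(1, nr)))
        nz <- occ > 0L
        rpieces[[length(rpieces) + 1L]] <- data.table::data.table(
          transcript_id = truth$transcript_id[i],
          position = pos0[nz], sample_id = sample_ids[j], count = occ[nz]
        )
      }
    }
    if (length(rpieces)) {
      pos_dt <- data.table::rbindlist(c(list(pos_dt), rpieces))
      pos_dt <- pos_dt[, list(count = sum(count)),
                       by = c("transcript_id", "position", "sample_id")]
    }
  }
  data.table::setkeyv(pos_dt, c("transcript_id", "position", "sample_id"))
  class(pos_dt) <- c("position_counts", class(pos_dt))

  sample_info <- data.frame(
    sample_id = sample_ids, condition = conditions, replicate = replicates,
    size_factor_rp = sf$rp, size_factor_rna = sf$rna,
    stringsAsFactors = FALSE
  )
  list(positions = pos_dt, rna = rna_se, sample_info = sample_info)
}

planted_size_factors <- function(config, nsamp) {
  if (!is.null(config$size_factors)) {
    sf <- config$size_factors
    stopifnot(length(sf$rp) == nsamp, length(sf$rna) == nsamp)
    return(list(rp = sf$rp, rna = sf$rna))
  }
  list(rp = exp(runif(nsamp, log(0.5), log(2))),
       rna = exp(runif(nsamp, log(0.5), log(2))))
}

#' Attach the uORF annotation to a truth table for uORF count generation
#'
#' [generate_counts()] simulates uORF occupancy only when the truth table
#' carries the uORF records of its `ribote_simdata`; this helper wires them
#' on (done automatically by [run_full()]).
#' @param truth truth table.
#' @param annotation the matching `annotation_set`.
#' @return truth with a `uorfs` attribute.
#' @export
with_uorfs <- function(truth, annotation) {
  attr(truth, "uorfs") <- annotation$uorfs
  truth
}
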