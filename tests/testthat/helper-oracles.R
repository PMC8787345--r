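# Independent oracles (brute force / enumeration) and small fixture
# builders shared across the test files. Oracles are deliberately written as
# plain loops, independent of the package's implementation paths.

# --- oracles ---------------------------------------------------------------

# max over all fully-contained w-nt window means within [0, tl), plain loop
oracle_max30 <- function(track, tl, w = 30L) {
  if (tl < w) return(NA_real_)
  best <- -Inf
  found <- FALSE
  for (i in 0:(tl - w)) {
    win <- track[(i + 1):(i + w)]
    if (!anyNA(win)) {
      found <- TRUE
      m <- sum(win) / w
      if (m > best) best <- m
    }
  }
  if (found) best else NA_real_
}

# exhaustive hypergeometric tail: P(|draw of size |b|| overlaps a by >= ov)
oracle_hyper_p <- function(universe, a, b) {
  ov <- length(intersect(a, b))
  draws <- utils::combn(universe, length(b))
  hits <- apply(draws, 2, function(d) length(intersect(d, a)) >= ov)
  mean(hits)
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group labelings
oracle_wilcoxon_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  U_obs <- sum(rank(vals)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(length(vals), n1)
  U_null <- apply(labelings, 2, function(idx) {
    sum(rank(vals)[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(U_null <= U_obs), mean(U_null >= U_obs)))
}

# textbook step-up BH, written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# --- fixture builders ------------------------------------------------------

# one-transcript annotation: TL of tl nt, CDS of cds_codons codons, optional
# short 3' UTR
tiny_annotation <- function(tl = 30L, cds_codons = 100L, utr3 = 10L,
                            gene = "gene1", tx = "gene1_t1", uorfs = NULL) {
  tr <- data.frame(
    gene_id = gene, transcript_id = tx,
    tx_length = tl + 3L * cds_codons + utr3,
    tl_length = tl, cds_start = tl, cds_length = 3L * cds_codons,
    stringsAsFactors = FALSE
  )
  annotation_set(tr, uorfs %||% ribote:::empty_uorf_frame())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# position counts with `per_codon` footprints on every CDS codon of `ann`,
# for the four standard samples
uniform_positions <- function(ann, per_codon = 1L,
                              samples = c("WT_1", "WT_2", "MUT_1", "MUT_2")) {
  tr <- ann$transcripts
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    L <- tr$cds_length[i] %/% 3L
    pos <- tr$cds_start[i] + 3L * (seq_len(L) - 1L)
    for (s in samples) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tr$transcript_id[i], position = pos,
        sample_id = s, count = per_codon, stringsAsFactors = FALSE
      )
    }
  }
  dt <- data.table::rbindlist(rows)
  data.table::setkeyv(dt, c("transcript_id", "position", "sample_id"))
  dt
}

# genes x 4 RNA count matrix with standard metadata
tiny_rna <- function(mat) {
  colnames(mat) <- c("WT_1", "WT_2", "MUT_1", "MUT_2")
  count_matrix(mat, "RNA", condition = c("WT", "WT", "MUT", "MUT"),
               replicate = c(1L, 2L, 1L, 2L))
}

# NB counts (var = mu + alpha mu^2) for a 2x2x2 TE design; returns rp/rna
# count_matrix pair with known per-condition TE ratio 2^log2_dte
simulate_pair <- function(n_genes, mu_rna = 200, alpha = 0.05, log2_dte = 0,
                          sf_rna = rep(1, 4), sf_rp = rep(1, 4),
                          depth = 2, seed = 1) {
  set.seed(seed)
  cond <- c("WT", "WT", "MUT", "MUT")
  te <- ifelse(cond == "MUT", 2^log2_dte, 1)
  rna <- sapply(seq_len(4), function(j) {
    rnbinom(n_genes, mu = mu_rna * sf_rna[j], size = 1 / alpha)
  })
  rp <- sapply(seq_len(4), function(j) {
    rnbinom(n_genes, mu = depth * mu_rna * te[j] * sf_rp[j], size = 1 / alpha)
  })
  ids <- sprintf("g%04d", seq_len(n_genes))
  rownames(rna) <- rownames(rp) <- ids
  colnames(rna) <- colnames(rp) <- paste0(cond, "_", c(1, 2, 1, 2))
  list(
    rna = count_matrix(rna, "RNA", cond, c(1, 2, 1, 2)),
    rp = count_matrix(rp, "RP", cond, c(1, 2, 1, 2))
  )
}
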