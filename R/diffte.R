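# Differential relative translational efficiency: normalization, dispersion
# estimation, the per-gene negative-binomial interaction test, BH adjustment
# and fold-change classification.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' rows positive in every sample) of the ratio of the gene's count to its
#' geometric mean across samples. If no all-positive row exists, falls back
#' to total-count ratios with a warning. Size factors are computed separately
#' per assay (footprint and RNA libraries have different composition).
#'
#' @param counts a [count_matrix()] SummarizedExperiment or plain matrix.
#' @return numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  mat <- if (is.matrix(counts)) counts else cm_counts(counts)
  if (ncol(mat) < 2) ribote_stop("size_factors: need >= 2 samples")
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) {
    warning("size_factors: no gene is positive in every sample; falling back to total-count ratios",
            call. = FALSE)
    tot <- colSums(mat)
    if (any(tot == 0)) ribote_stop("size_factors: a sample has zero total counts")
    return(setNames(tot / geomean(tot), colnames(mat)))
  }
  lg <- log(mat[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  setNames(apply(exp(lg - ref), 2, median), colnames(mat))
}

#' Normalize a count matrix by size factors
#'
#' @param counts a [count_matrix()] SummarizedExperiment or matrix.
#' @param sf per-sample size factors; computed via [size_factors()] when
#'   omitted.
#' @return list with `mat` (normalized real-valued matrix) and `sf`.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  mat <- if (is.matrix(counts)) counts else cm_counts(counts)
  if (is.null(sf)) sf <- size_factors(mat)
  if (any(sf <= 0)) ribote_stop("normalize_counts: size factors must be > 0")
  list(mat = sweep(mat, 2, sf, `/`), sf = sf)
}

#' Relative translational efficiency per condition
#'
#' TE_rel = normalized footprint count / normalized RNA count, computed per
#' replicate (replicates paired by index within condition) and averaged
#' within condition. TE_rel is relative to each library's mRNA population;
#' it does not measure absolute translational efficiency. Genes with zero
#' RNA in a replicate get a missing ratio for that replicate (dropped from
#' the within-condition mean; all-missing genes yield `NA`).
#'
#' @param rp,rna [count_matrix()] SummarizedExperiments of footprint and RNA
#'   counts with matching gene universes and a shared condition/replicate
#'   layout.
#' @param sf_rp,sf_rna optional size factors per assay.
#' @return data.frame: gene_id, te_WT, te_MUT, log2_te_ratio.
#' @export
compute_te_rel <- function(rp, rna, sf_rp = NULL, sf_rna = NULL) {
  genes <- intersect(rownames(rp), rownames(rna))
  if (length(genes) == 0) ribote_stop("compute_te_rel: empty shared gene universe")
  nrp <- normalize_counts(cm_counts(rp)[genes, , drop = FALSE], sf_rp %||% size_factors(rp))
  nrna <- normalize_counts(cm_counts(rna)[genes, , drop = FALSE], sf_rna %||% size_factors(rna))
  cond_rp <- cm_condition(rp); cond_rna <- cm_condition(rna)
  rep_rp <- SummarizedExperiment::colData(rp)$replicate
  rep_rna <- SummarizedExperiment::colData(rna)$replicate
  te_cond <- function(cond) {
    jr <- which(cond_rp == cond)[order(rep_rp[cond_rp == cond])]
    jn <- which(cond_rna == cond)[order(rep_rna[cond_rna == cond])]
    if (length(jr) != length(jn)) {
      ribote_stop("compute_te_rel: unmatched replicate layout between assays")
    }
    ratio <- nrp$mat[, jr, drop = FALSE] / nrna$mat[, jn, drop = FALSE]
    ratio[!is.finite(ratio)] <- NA
    rowMeans(ratio, na.rm = TRUE)
  }
  te_wt <- te_cond("WT"); te_mut <- te_cond("MUT")
  te_wt[is.nan(te_wt)] <- NA; te_mut[is.nan(te_mut)] <- NA
  n_missing <- sum(is.na(te_wt) | is.na(te_mut))
  if (n_missing > 0) {
    message(sprintf("compute_te_rel: %d gene(s) with missing TE (zero RNA)",
                    n_missing))
  }
  data.frame(gene_id = genes, te_WT = te_wt, te_MUT = te_mut,
             log2_te_ratio = log2(te_mut / te_wt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene NB dispersion with trend shrinkage
#'
#' Method-of-moments dispersion per gene from normalized counts within each
#' condition, `max((var - mean) / mean^2, 1e-8)` pooled across conditions
#' (weights = residual df), then shrunk toward a mean-dispersion trend
#' `a0 + a1 / mean` fitted across genes: final = (1 - weight) * gene +
#' weight * trend. Genes with zero variance in every condition are assigned
#' the trend value and flagged.
#'
#' @param counts a [count_matrix()] SummarizedExperiment (one assay).
#' @param sf optional size factors.
#' @param shrink_weight weight on the trend (default 0.5).
#' @return data.frame: gene_id, base_mean, dispersion_raw, dispersion_trend,
#'   dispersion, degenerate (logical).
#' @export
estimate_dispersion <- function(counts, sf = NULL, shrink_weight = 0.5) {
  cond <- cm_condition(counts)
  if (min(table(cond)) < 2) {
    ribote_stop("estimate_dispersion: need >= 2 replicates per condition")
  }
  nc <- normalize_counts(counts, sf)
  y <- nc$mat
  base_mean <- rowMeans(y)
  raw <- rep(NA_real_, nrow(y)); wsum <- rep(0, nrow(y))
  num <- rep(0, nrow(y))
  degenerate <- rep(TRUE, nrow(y))
  for (cn in unique(cond)) {
    yc <- y[, cond == cn, drop = FALSE]
    m <- rowMeans(yc); v <- apply(yc, 1, var)
    df <- ncol(yc) - 1
    ok <- m > 0
    est <- ifelse(ok, (v - m) / m^2, NA_real_)
    num <- num + ifelse(is.na(est), 0, est * df)
    wsum <- wsum + ifelse(is.na(est), 0, df)
    degenerate <- degenerate & (v == 0)
  }
  raw <- ifelse(wsum > 0, pmax(num / wsum, 1e-8), NA_real_)

  fit_ok <- !is.na(raw) & raw > 1e-8 & base_mean > 0 & !degenerate
  trend_fun <- fit_dispersion_trend(base_mean[fit_ok], raw[fit_ok])
  trend <- trend_fun(pmax(base_mean, 1e-8))
  disp <- (1 - shrink_weight) * raw + shrink_weight * trend
  disp[degenerate | is.na(raw)] <- trend[degenerate | is.na(raw)]
  disp <- pmax(disp, 1e-8)
  data.frame(gene_id = rownames(y), base_mean = base_mean,
             dispersion_raw = raw, dispersion_trend = trend,
             dispersion = disp, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

# alpha(mu) = a0 + a1/mu fitted by least squares with nonnegativity clamps;
# falls back to the median raw dispersion when too few informative genes.
fit_dispersion_trend <- function(mu, alpha) {
  if (length(mu) >= 10) {
    fit <- try(lm(alpha ~ I(1 / mu)), silent = TRUE)
    if (!inherits(fit, "try-error") && !anyNA(coef(fit))) {
      a0 <- max(coef(fit)[1], 1e-8)
      a1 <- max(coef(fit)[2], 0)
      return(function(m) a0 + a1 / m)
    }
  }
  med <- if (length(alpha)) median(alpha) else 1e-2
  function(m) rep(max(med, 1e-8), length(m))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement; `NA` p-values are excluded from
#' the ranking (and the effective number of tests) and propagate as `NA`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values, same length/order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    ribote_stop("adjust_bh: p-values must be in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  m <- sum(ok)
  if (m == 0) return(out)
  pp <- p[ok]
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(pp[o] * m / (m:1)))[ro]
  out
}

#' Classify a significant TE_rel change by fold-change magnitude
#'
#' Significant genes (padj < `alpha`) are labelled by the magnitude of their
#' TE_rel ratio `2^log2_dte`: `up100` (>= 2x increase), `up50` (>= 1.5x),
#' `down100` (<= 1/2), `down50` (<= 1/1.5), `sig_small` (significant but
#' below 50% change); non-significant genes are `ns`.
#'
#' @param log2_dte log2 TE_rel ratio (mutant vs WT).
#' @param padj BH-adjusted p-value.
#' @param alpha significance threshold (default 0.05).
#' @return character vector of categories.
#' @export
classify_te_change <- function(log2_dte, padj, alpha = 0.05) {
  ratio <- 2^log2_dte
  out <- rep("ns", length(log2_dte))
  sig <- !is.na(padj) & padj < alpha & !is.na(log2_dte)
  out[sig] <- "sig_small"
  out[sig & ratio >= 1.5] <- "up50"
  out[sig & ratio >= 2] <- "up100"
  out[sig & ratio <= 1 / 1.5] <- "down50"
  out[sig & ratio <= 0.5] <- "down100"
  out
}

#' Test per-gene changes in relative translational efficiency
#'
#' Fits, per gene, a negative-binomial log-linear model over the eight (or
#' `2 x 2 x n_rep`) libraries with offsets `log(size factor)` and design
#' `intercept + assay + condition + assay:condition`; the interaction
#' coefficient is the log fold change of TE_rel between mutant and WT
#' (`log2_dte = coef / ln 2`). Dispersions are per gene and assay (known
#' during fitting, from [estimate_dispersion()]); inference is a Wald test
#' with normal reference, adjusted across genes by Benjamini-Hochberg.
#'
#' Genes with an empty design cell (all-zero counts in some assay x
#' condition) or non-converging fits are reported with `NA` statistics and
#' counted in the `convergence` attribute.
#'
#' @param rp,rna footprint and RNA [count_matrix()] SummarizedExperiments on
#'   a shared (already filtered) gene universe.
#' @param dispersions optional list(rp=, rna=) as from
#'   [estimate_dispersion()].
#' @param sf optional list(rp=, rna=) of size factors.
#' @param shrink_weight trend-shrinkage weight for dispersion estimation.
#' @param alpha significance threshold used for category labels.
#' @return data.frame of class `te_result`: gene_id, base_mean, log2_dte,
#'   se, wald_stat, p, padj, category. Attribute `convergence` gives the
#'   fraction of genes with a successful fit.
#' @export
test_delta_te <- function(rp, rna, dispersions = NULL, sf = NULL,
                          shrink_weight = 0.5, alpha = 0.05) {
  genes <- intersect(rownames(rp), rownames(rna))
  if (length(genes) == 0) ribote_stop("test_delta_te: empty shared gene universe")
  if (length(genes) < nrow(rp) || length(genes) < nrow(rna)) {
    warning("test_delta_te: gene universes differ between assays; using the intersection",
            call. = FALSE)
  }
  rp_mat <- cm_counts(rp)[genes, , drop = FALSE]
  rna_mat <- cm_counts(rna)[genes, , drop = FALSE]
  if (is.null(sf)) sf <- list(rp = size_factors(rp_mat), rna = size_factors(rna_mat))
  if (is.null(dispersions)) {
    dispersions <- list(
      rp = estimate_dispersion(subset_cm(rp, genes), sf$rp, shrink_weight),
      rna = estimate_dispersion(subset_cm(rna, genes), sf$rna, shrink_weight)
    )
  }
  disp_rp <- dispersions$rp$dispersion[match(genes, dispersions$rp$gene_id)]
  disp_rna <- dispersions$rna$dispersion[match(genes, dispersions$rna$gene_id)]

  cond <- c(cm_condition(rna), cm_condition(rp))
  is_rp <- rep(c(0, 1), c(ncol(rna_mat), ncol(rp_mat)))
  is_mut <- as.numeric(cond == "MUT")
  X <- cbind(1, is_rp, is_mut, is_rp * is_mut)
  offset <- log(c(sf$rna, sf$rp))

  n <- length(genes)
  est <- se <- rep(NA_real_, n)
  converged <- rep(FALSE, n)
  for (g in seq_len(n)) {
    y <- c(rna_mat[g, ], rp_mat[g, ])
    alpha_obs <- c(rep(disp_rna[g], ncol(rna_mat)), rep(disp_rp[g], ncol(rp_mat)))
    cell <- interaction(is_rp, is_mut)
    if (any(tapply(y, cell, sum) == 0)) next  # interaction not estimable
    fit <- nb_irls(y, X, offset, alpha_obs)
    if (fit$converged) {
      est[g] <- fit$beta[4]; se[g] <- fit$se[4]; converged[g] <- TRUE
    }
  }
  n_failed <- sum(!converged)
  if (n_failed > 0) {
    message(sprintf("test_delta_te: %d/%d gene(s) without a converged fit (reported NA)",
                    n_failed, n))
  }
  wald <- est / se
  p <- 2 * pnorm(-abs(wald))
  padj <- adjust_bh(p)
  base_mean <- rowMeans(cbind(sweep(rna_mat, 2, sf$rna, `/`),
                              sweep(rp_mat, 2, sf$rp, `/`)))
  res <- data.frame(
    gene_id = genes, base_mean = base_mean,
    log2_dte = est / log(2), se = se / log(2),
    wald_stat = wald, p = p, padj = padj,
    category = classify_te_change(est / log(2), padj, alpha),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "convergence") <- mean(converged)
  attr(res, "size_factors") <- sf
  class(res) <- c("te_result", "data.frame")
  res
}

subset_cm <- function(se, genes) se[genes, ]

# IRLS for an NB log-linear model with known per-observation dispersion.
# Working weights mu / (1 + alpha * mu); returns Wald SEs from the observed
# information at convergence.
nb_irls <- function(y, X, offset, alpha_obs, max_iter = 50, tol = 1e-10) {
  beta <- tryCatch(
    qr.solve(X, log(pmax(y, 0.5)) - offset),
    error = function(e) rep(0, ncol(X))
  )
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha_obs * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtWX <- crossprod(X, w * X)
    step <- tryCatch(solve(XtWX, crossprod(X, w * z)),
                     error = function(e) NULL)
    if (is.null(step)) return(list(converged = FALSE))
    delta <- max(abs(step - beta))
    beta <- drop(step)
    if (!all(is.finite(beta))) return(list(converged = FALSE))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) return(list(converged = FALSE))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(list(converged = FALSE))
  list(beta = beta, se = sqrt(diag(cov)), converged = TRUE)
}
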