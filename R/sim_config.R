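#' Simulation configuration
#'
#' Builds the configuration object consumed by [generate_transcriptome()] and
#' [generate_counts()]. Defaults describe a budding-yeast-like transcriptome
#' under a ribosome-profiling experiment with two biological replicates per
#' condition: log-normal transcript-leader (TL) lengths with median ~75 nt,
#' log-normal CDS lengths with median ~380 codons (floored at 25 codons),
#' log-normal mean mRNA counts, and a DESeq2-style dispersion trend
#' `alpha(mu) = asymptotic + extra_poisson / mu`.
#'
#' @param n_genes number of genes (>= 10 required downstream).
#' @param n_replicates biological replicates per condition (>= 2).
#' @param tl_length_dist list(meanlog, sdlog, min, max) for TL length in nt.
#' @param cds_length_dist list(meanlog, sdlog, min) for CDS length in codons
#'   (min 25 codons enforced).
#' @param utr3_length_dist list(meanlog, sdlog) for 3'-UTR length in nt.
#' @param uorf_rate expected number of uORFs per gene (Poisson).
#' @param mean_expression_dist list(meanlog, sdlog) for true mean RNA counts.
#' @param dispersion_model list(asymptotic, extra_poisson): per-gene NB
#'   dispersion drawn around the trend `asymptotic + extra_poisson/mean`
#'   (multiplicative log-normal jitter `sdlog_jitter`).
#' @param effect_model list of coefficients linking true log2 dTE_rel to
#'   planted features plus noise: `intercept`, `utr_length` (per nt, applied
#'   to centred TL length), `max30` (per PARS unit, centred), `context_score`
#'   (per unit of planted context strength in \[0,1\], centred), `sd` (noise SD
#'   in log2 units).
#' @param frac_null fraction of genes with true log2 dTE_rel exactly 0.
#' @param frac_dominant fraction of genes constructed to pass the 40%/2x
#'   dominant-isoform rule.
#' @param context_strength_dist list(shape1, shape2): Beta distribution of the
#'   per-gene Kozak-context strength in \[0,1\] (1 = consensus `AAAAAA|AUG|G`).
#' @param pars_model list(baseline_mean, noise_sd, structured_rate,
#'   structured_effect, window, missing_rate): per-nt PARS scores are Gaussian
#'   noise around `baseline_mean`; with probability `structured_rate` a gene
#'   with TL >= `window` nt receives one planted structured window of
#'   `window` nt elevated by `structured_effect`.
#' @param ramp list(enabled, fold): optional cycloheximide-like 5' ramp that
#'   multiplies footprint density in the first 15 codons by `fold`. Off by
#'   default; exists to exercise the codon-exclusion rule.
#' @param size_factors NULL (plant log-uniform in \[0.5, 2\] per sample) or a
#'   list(rp = numeric, rna = numeric) of explicit per-sample factors.
#' @param rp_depth_factor footprint library depth relative to RNA depth.
#' @param te_wt_dist list(meanlog, sdlog) for the WT translational efficiency
#'   multiplier.
#' @param uorf_load mean uORF footprint occupancy as a fraction of the host
#'   gene's CDS footprint mean.
#' @param external_cor target correlation between the true log2 dTE_rel and a
#'   generated "external mutant" dTE table (emulates published tables from
#'   other initiation-factor mutants).
#' @param seed integer seed; every generator derives its stream from it.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' @export
sim_config <- function(n_genes,
                       n_replicates = 2,
                       tl_length_dist = list(meanlog = log(75), sdlog = 0.6,
                                             min = 12, max = 1500),
                       cds_length_dist = list(meanlog = log(380), sdlog = 0.45,
                                              min = 25),
                       utr3_length_dist = list(meanlog = log(100), sdlog = 0.4),
                       uorf_rate = 0.3,
                       mean_expression_dist = list(meanlog = log(150), sdlog = 1),
                       dispersion_model = list(asymptotic = 0.01,
                                               extra_poisson = 1.5,
                                               sdlog_jitter = 0.2),
                       effect_model = list(intercept = 0, utr_length = 0,
                                           max30 = 0, context_score = 0,
                                           sd = 0.35),
                       frac_null = 0.8,
                       frac_dominant = 0.7,
                       context_strength_dist = list(shape1 = 2, shape2 = 2),
                       pars_model = list(baseline_mean = -0.5, noise_sd = 1,
                                         structured_rate = 0.3,
                                         structured_effect = 2.5,
                                         window = 30, missing_rate = 0),
                       ramp = list(enabled = FALSE, fold = 5),
                       size_factors = NULL,
                       rp_depth_factor = 2,
                       te_wt_dist = list(meanlog = 0, sdlog = 0.3),
                       uorf_load = 0.1,
                       external_cor = 0.6,
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    tl_length_dist = tl_length_dist, cds_length_dist = cds_length_dist,
    utr3_length_dist = utr3_length_dist, uorf_rate = uorf_rate,
    mean_expression_dist = mean_expression_dist,
    dispersion_model = dispersion_model, effect_model = effect_model,
    frac_null = frac_null, frac_dominant = frac_dominant,
    context_strength_dist = context_strength_dist, pars_model = pars_model,
    ramp = ramp, size_factors = size_factors,
    rp_depth_factor = rp_depth_factor, te_wt_dist = te_wt_dist,
    uorf_load = uorf_load, external_cor = external_cor,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- unlist(cfg[c("tl_length_dist", "cds_length_dist",
                             "utr3_length_dist", "mean_expression_dist",
                             "dispersion_model", "effect_model",
                             "context_strength_dist", "te_wt_dist")])
  if (!all(is.finite(num_fields))) {
    ribote_stop("sim_config: all distribution parameters must be finite")
  }
  if (!is.numeric(cfg$frac_null) || cfg$frac_null < 0 || cfg$frac_null > 1) {
    ribote_stop("sim_config: frac_null must be in [0, 1]")
  }
  if (!is.numeric(cfg$frac_dominant) || cfg$frac_dominant < 0 ||
      cfg$frac_dominant > 1) {
    ribote_stop("sim_config: frac_dominant must be in [0, 1]")
  }
  if (cfg$n_replicates < 2) {
    ribote_stop("sim_config: n_replicates must be >= 2 (dispersion estimation needs replication)")
  }
  if (cfg$uorf_rate < 0) ribote_stop("sim_config: uorf_rate must be >= 0")
  if (cfg$cds_length_dist$min < 25) {
    ribote_stop("sim_config: cds_length_dist$min must be >= 25 codons")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d genes, %d replicates/condition, frac_null=%.2f, seed=%d\n",
    x$n_genes, x$n_replicates, x$frac_null, x$seed
  ))
  invisible(x)
}
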