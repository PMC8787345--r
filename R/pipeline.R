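# End-to-end orchestration: simulate -> write/read -> quantify -> diffte ->
# features -> assoc, with a reproducibility manifest and truth evaluation.

#' Run the full analysis pipeline
#'
#' With a `sim_config`, generates a synthetic dataset, writes every external
#' format to `outdir/sim/`, reads them back (so the round trip is part of
#' every run), then quantifies footprints, applies the mRNA expression
#' filter, tests per-gene dTE_rel, builds the feature table, computes the
#' association statistics, evaluates estimates against the planted truth,
#' and writes `te_results.tsv`, `features.tsv`, `assoc.json`,
#' `evaluation.json` and `manifest.json` to `outdir`.
#'
#' Any stage failure aborts with the stage name and cause; outputs written
#' before the failure are retained next to a `FAILED_<stage>` marker file.
#'
#' @param config a [sim_config()] (simulation-driven run) or a run-config
#'   list as returned by [load_run_config()] (file-driven run).
#' @param outdir output directory (created if needed).
#' @param padj_threshold significance threshold (default 0.05).
#' @param rna_filter_threshold minimum total mRNA reads per strain pair
#'   (default 128).
#' @param plots write PDF plots (default FALSE).
#' @return list of class `ribote_run`: te, features, assoc, evaluation,
#'   manifest, inputs.
#' @export
run_full <- function(config, outdir, padj_threshold = 0.05,
                     rna_filter_threshold = 128, plots = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(outdir, paste0("FAILED_", name)))
      ribote_stop(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)), class = "ribote_stage_error")
    })
  }

  simulated <- inherits(config, "sim_config")
  drops <- list()

  if (simulated) {
    inputs <- stage("simulate", {
      sim <- generate_transcriptome(config)
      cnt <- generate_counts(sim, config)
      simdir <- file.path(outdir, "sim")
      paths <- write_simdata(sim, cnt, simdir)
      read_simdata(paths)
    })
    external <- inputs$external
    truth <- inputs$truth
  } else {
    inputs <- stage("load", load_inputs(config))
    external <- inputs$external
    truth <- inputs$truth  # NULL for real data
  }

  quant <- stage("quantify", {
    rp <- count_cds(inputs$positions, inputs$annotation)
    uorf_rp <- if (nrow(inputs$annotation$uorfs) > 0) {
      count_uorf(inputs$positions, inputs$annotation)
    }
    kept <- filter_low_expression(inputs$rna, rna_filter_threshold,
                                  require_four = ncol(inputs$rna) == 4)
    drops$empty_window <- nrow(inputs$annotation$transcripts) - nrow(rp)
    drops$low_expression <- nrow(inputs$rna) - length(kept)
    kept_rp <- intersect(kept, rownames(rp))
    list(rp = rp[kept_rp, ], rna = inputs$rna[kept, ], uorf_rp = uorf_rp,
         kept = kept)
  })

  te <- stage("diffte", {
    test_delta_te(quant$rp, quant$rna, alpha = padj_threshold)
  })

  features <- stage("features", {
    build_feature_table(inputs$annotation, inputs$sequences, inputs$pars,
                        isoforms = inputs$isoforms,
                        closed_loop = inputs$closed_loop)
  })
  drops$no_dominant_isoform <- sum(is.na(features$tl_length))

  assoc <- stage("assoc", {
    assoc_report(te, features, external = external,
                 alpha = padj_threshold)
  })

  evaluation <- if (!is.null(truth)) {
    stage("evaluate", evaluate_against_truth(te, truth,
                                             alpha = padj_threshold))
  }

  manifest <- stage("manifest", {
    cfg_file <- file.path(outdir, "config.yaml")
    yaml::write_yaml(unclass_recursive(config), cfg_file)
    list(
      package_version = as.character(packageVersion("ribote")),
      config_md5 = unname(tools::md5sum(cfg_file)),
      seed = if (simulated) config$seed else config$seed %||% NA,
      thresholds = list(padj = padj_threshold,
                        rna_filter = rna_filter_threshold),
      n_genes_annotated = nrow(inputs$annotation$transcripts),
      n_genes_after_filter = length(quant$kept),
      n_genes_tested = nrow(te),
      drop_counts = drops
    )
  })

  stage("write", {
    write_tsv(te, file.path(outdir, "te_results.tsv"))
    write_tsv(features, file.path(outdir, "features.tsv"))
    jsonlite::write_json(assoc_to_json(assoc), file.path(outdir, "assoc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(evaluation)) {
      jsonlite::write_json(evaluation, file.path(outdir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  if (plots) stage("plots", write_run_plots(te, features, assoc, outdir))

  structure(list(te = te, features = features, assoc = assoc,
                 evaluation = evaluation, manifest = manifest,
                 inputs = inputs),
            class = "ribote_run")
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

#' Association report across the standard feature set
#'
#' Spearman correlations of log2 dTE_rel with TL length, the five PARS
#' window statistics, context score, CDS length and transcript length;
#' Wilcoxon contrasts of TL length between dTE categories; ANOVA + Tukey of
#' PARS max30 and of dTE by closed-loop group; and, when an external table
#' is available, the Pearson/overlap comparison.
#'
#' @param te `te_result` table.
#' @param features `feature_table`.
#' @param external optional external dTE data.frame.
#' @param alpha significance threshold.
#' @return list of class `assoc_report`.
#' @export
assoc_report <- function(te, features, external = NULL, alpha = 0.05) {
  f <- features[match(te$gene_id, features$gene_id), ]
  feature_cols <- c("tl_length", "pars_mean_utr", "pars_first30",
                    "pars_start30", "pars_plus30", "pars_max30",
                    "context_score", "cds_length", "transcript_length")
  correlations <- lapply(setNames(feature_cols, feature_cols), function(col) {
    correlate(f[[col]], te$log2_dte, method = "spearman")
  })

  dir3 <- te_direction(te$category)
  group_tests <- list()
  if (length(unique(dir3[!is.na(dir3)])) >= 2) {
    have <- !is.na(f$tl_length) & !is.na(dir3)
    pairs <- list(c("down", "ns"), c("up", "ns"), c("down", "up"))
    wil <- lapply(pairs, function(pr) {
      sel <- have & dir3 %in% pr
      if (length(unique(dir3[sel])) == 2) {
        compare_two_groups(f$tl_length[sel], dir3[sel])
      }
    })
    names(wil) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    group_tests$tl_length_wilcoxon <- wil[!vapply(wil, is.null, logical(1))]
  }
  if (all(c("down", "up", "ns") %in% dir3) &&
      sum(!is.na(f$pars_max30) & !is.na(dir3)) > 6) {
    sel <- !is.na(f$pars_max30) & !is.na(dir3)
    if (all(table(dir3[sel]) >= 2) && length(unique(dir3[sel])) >= 3) {
      group_tests$pars_max30_anova <-
        compare_multi_groups(f$pars_max30[sel], dir3[sel])
    }
  }
  if (!all(is.na(f$closed_loop_group))) {
    sel <- !is.na(f$closed_loop_group) & !is.na(te$log2_dte)
    if (length(unique(f$closed_loop_group[sel])) >= 3 &&
        all(table(f$closed_loop_group[sel]) >= 2)) {
      group_tests$closed_loop_anova <-
        compare_multi_groups(te$log2_dte[sel],
                             paste0("group", f$closed_loop_group[sel]))
    }
  }

  ext_cmp <- NULL
  clustering <- NULL
  if (!is.null(external)) {
    ext_cmp <- compare_external(te, external, alpha = alpha)
    shared <- intersect(te$gene_id, external$gene_id)
    sig <- shared[!is.na(te$padj[match(shared, te$gene_id)]) &
                    te$padj[match(shared, te$gene_id)] < alpha]
    if (length(sig) >= 2) {
      m <- cbind(self = te$log2_dte[match(sig, te$gene_id)],
                 external = external$log2_dte[match(sig, external$gene_id)])
      rownames(m) <- sig
      clustering <- cluster_delta_te(m)
    }
  }

  structure(list(correlations = correlations, group_tests = group_tests,
                 external = ext_cmp, clustering = clustering),
            class = "assoc_report")
}

#' Collapse dTE categories to direction labels
#' @param category character vector of `te_result` categories.
#' @return "up", "down", "ns" (sig_small maps to its sign-free "ns"-adjacent
#'   bucket: it is significant but below the 50% bands, so it is excluded
#'   from directional contrasts as `NA`).
#' @export
te_direction <- function(category) {
  out <- rep(NA_character_, length(category))
  out[category %in% c("up50", "up100")] <- "up"
  out[category %in% c("down50", "down100")] <- "down"
  out[category == "ns"] <- "ns"
  out
}

assoc_to_json <- function(assoc) {
  list(
    correlations = lapply(assoc$correlations, function(cr) {
      list(method = cr$method, rho = cr$rho, p = cr$p, n = cr$n)
    }),
    group_tests = unclass_recursive(assoc$group_tests),
    external = if (!is.null(assoc$external)) list(
      pearson_rho = assoc$external$correlation$rho,
      pearson_p = assoc$external$correlation$p,
      overlap_up_p = assoc$external$overlap_up$p_hyper,
      overlap_down_p = assoc$external$overlap_down$p_hyper,
      n_shared = assoc$external$n_shared
    )
  )
}

#' Evaluate dTE estimates against simulation truth
#'
#' @param te `te_result` table.
#' @param truth truth table from [generate_transcriptome()].
#' @param alpha significance threshold for calls.
#' @return list: n_tested, n_calls, empirical_fdr (false calls / calls, 0
#'   when no calls), frac_called, sensitivity_by_bin (|true log2 dTE| bins),
#'   bias, rmse, cor_true_est.
#' @export
evaluate_against_truth <- function(te, truth, alpha = 0.05) {
  if (!all(te$gene_id %in% truth$gene_id)) {
    ribote_stop("evaluate_against_truth: tested genes missing from truth table")
  }
  tr <- truth[match(te$gene_id, truth$gene_id), ]
  called <- !is.na(te$padj) & te$padj < alpha
  false_call <- called & tr$is_null
  bins <- cut(abs(tr$true_log2_dte), c(0, 0.25, 0.5, 1, Inf),
              right = TRUE, include.lowest = FALSE,
              labels = c("(0,0.25]", "(0.25,0.5]", "(0.5,1]", ">1"))
  sens <- tapply(called[!tr$is_null], bins[!tr$is_null],
                 function(z) if (length(z)) mean(z) else NA_real_)
  ok_est <- !is.na(te$log2_dte)
  err <- te$log2_dte[ok_est] - tr$true_log2_dte[ok_est]
  list(
    n_tested = nrow(te),
    n_calls = sum(called),
    empirical_fdr = if (sum(called) > 0) sum(false_call) / sum(called) else 0,
    frac_called = mean(called),
    sensitivity_by_bin = as.list(sens),
    bias = mean(err),
    rmse = sqrt(mean(err^2)),
    cor_true_est = if (sd(tr$true_log2_dte[ok_est]) > 0)
      cor(te$log2_dte[ok_est], tr$true_log2_dte[ok_est]) else NA_real_
  )
}

#' Write all simulated datasets to their external formats
#'
#' @param sim `ribote_simdata` from [generate_transcriptome()].
#' @param cnt output of [generate_counts()].
#' @param dir target directory.
#' @return named list of written paths.
#' @export
write_simdata <- function(sim, cnt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    annotation = file.path(dir, "annotation.gff3"),
    fasta = file.path(dir, "transcripts.fa"),
    pars = file.path(dir, "pars.bedgraph"),
    isoforms = file.path(dir, "isoforms.tsv"),
    closed_loop = file.path(dir, "closed_loop.tsv"),
    positions = file.path(dir, "rp_positions.tsv"),
    rna = file.path(dir, "rna_counts.tsv"),
    truth = file.path(dir, "truth.tsv"),
    external = file.path(dir, "external_dte.tsv")
  )
  write_annotation(sim$annotation, p$annotation)
  write_sequences(sim$sequences, p$fasta)
  write_pars(sim$pars, p$pars)
  write_isoforms(sim$isoforms, p$isoforms)
  write_tsv(sim$closed_loop, p$closed_loop)
  write_position_counts(cnt$positions, p$positions)
  write_count_table(cnt$rna, p$rna)
  write_truth(sim$truth, p$truth)
  write_tsv(generate_external_dte(sim$truth, sim$config), p$external)
  p
}

#' Read a full input bundle from paths
#' @param paths named list as produced by [write_simdata()] (or assembled by
#'   hand / from a run config); `truth` and `external` are optional.
#' @return list: annotation, sequences, pars, isoforms, closed_loop,
#'   positions, rna, truth, external.
#' @export
read_simdata <- function(paths) {
  ann <- read_annotation(paths$annotation)
  list(
    annotation = ann,
    sequences = read_sequences(paths$fasta),
    pars = read_pars(paths$pars, ann),
    isoforms = read_isoforms(paths$isoforms),
    closed_loop = read_closed_loop(paths$closed_loop),
    positions = read_position_counts(paths$positions, ann),
    rna = read_count_table(paths$rna, "RNA"),
    truth = if (!is.null(paths$truth) && file.exists(paths$truth))
      read_truth(paths$truth),
    external = if (!is.null(paths$external) && file.exists(paths$external))
      read_external_dte(paths$external)
  )
}

load_inputs <- function(config) {
  paths <- config$paths
  needed <- c("annotation", "fasta", "pars", "isoforms", "closed_loop",
              "positions", "rna")
  missing <- needed[!vapply(needed, function(k)
    !is.null(paths[[k]]) && file.exists(paths[[k]]), logical(1))]
  if (length(missing) > 0) {
    ribote_stop(sprintf("run config: missing input path(s): %s",
                        paste(missing, collapse = ", ")))
  }
  read_simdata(paths)
}

#' Load and validate a YAML run configuration
#'
#' A file-driven run config lists input `paths` (annotation, fasta, pars,
#' isoforms, closed_loop, positions, rna, optionally truth/external),
#' `thresholds` (padj, rna_filter) and a `seed`.
#'
#' @param path YAML file.
#' @return validated run-config list.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- cfg$thresholds
  if (!is.null(thr)) {
    if (any(unlist(thr) <= 0)) ribote_stop("run config: thresholds must be positive")
  }
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) {
      ribote_stop(sprintf("run config: input path does not exist: %s", p))
    }
  }
  cfg
}
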