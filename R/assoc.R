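# Association layer: correlations, hypergeometric set overlaps, group
# contrasts (Wilcoxon, ANOVA + Tukey HSD), hierarchical clustering of dTE
# profiles, and cross-dataset comparison.

#' Correlate two paired vectors
#'
#' Pearson, or Spearman computed as Pearson on average ranks (ties share the
#' mean rank). Missing values are dropped pairwise. The p-value uses the
#' t-approximation with n - 2 degrees of freedom (for Spearman, applied to
#' the rank correlation); `|rho| = 1` gives p = 0.
#'
#' @param x,y numeric vectors of equal length.
#' @param method "spearman" (default) or "pearson".
#' @return list of class `correlation_result`: method, rho, p, n; rho/p are
#'   `NA` with a `reason` when either vector has zero variance or n < 3.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) ribote_stop("correlate: x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  res <- structure(list(method = method, rho = NA_real_, p = NA_real_, n = n),
                   class = "correlation_result")
  if (n < 3) { res$reason <- "fewer than 3 complete pairs"; return(res) }
  if (sd(x) == 0 || sd(y) == 0) {
    res$reason <- "zero variance"; return(res)
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  rho <- cor(x, y)
  res$rho <- rho
  if (abs(rho) >= 1) {
    res$p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    res$p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s rho = %.4f (n = %d, p = %.3g)%s\n", x$method,
              x$rho, x$n, x$p,
              if (!is.null(x$reason)) paste0(" [", x$reason, "]") else ""))
  invisible(x)
}

#' Hypergeometric test for gene-set overlap
#'
#' Tests whether the overlap between two gene sets within a universe is
#' larger than expected by chance: `p = P(X >= n_overlap)` with
#' `X ~ Hypergeometric(N = |universe|, K = |a|, n = |b|)`, computed exactly.
#'
#' @param a,b character vectors of gene ids (each a subset of `universe`).
#' @param universe character vector of all eligible gene ids.
#' @return list of class `overlap_result`: n_universe, n_a, n_b, n_overlap,
#'   p_hyper.
#' @export
overlap_test <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  bad <- c(setdiff(a, universe), setdiff(b, universe))
  if (length(bad) > 0) {
    ribote_stop(sprintf("overlap_test: id(s) outside the universe: %s",
                        paste(head(bad, 5), collapse = ", ")))
  }
  N <- length(universe); K <- length(a); nb <- length(b)
  ov <- length(intersect(a, b))
  p <- stats::phyper(ov - 1, K, N - K, nb, lower.tail = FALSE)
  structure(list(n_universe = N, n_a = K, n_b = nb, n_overlap = ov,
                 p_hyper = p), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d (|a| = %d, |b| = %d, N = %d): p_hyper = %.3g\n",
              x$n_overlap, x$n_a, x$n_b, x$n_universe, x$p_hyper))
  invisible(x)
}

#' Two-group comparison (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test; the exact null distribution is used when the
#' smaller group has at most `exact_max` observations and there are no ties,
#' otherwise the normal approximation with continuity correction.
#'
#' @param values numeric vector.
#' @param labels group labels (exactly two distinct values).
#' @param exact_max largest min-group size for the exact branch (default 8).
#' @return list of class `group_test_result`: test, groups, statistic, p.
#' @export
compare_two_groups <- function(values, labels, exact_max = 8) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  groups <- sort(unique(labels))
  if (length(groups) != 2) ribote_stop("compare_two_groups: need exactly two groups")
  x <- values[labels == groups[1]]; y <- values[labels == groups[2]]
  if (length(x) == 0 || length(y) == 0) ribote_stop("compare_two_groups: empty group")
  ties <- anyDuplicated(values) > 0
  use_exact <- min(length(x), length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  structure(list(test = "wilcoxon", groups = groups,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 exact = use_exact),
            class = "group_test_result")
}

#' Multi-group comparison (one-way ANOVA with Tukey HSD)
#'
#' One-way ANOVA F-test across three or more groups, followed by Tukey
#' honest-significant-difference pairwise comparisons (studentized range
#' distribution). All-identical data yields an undefined F, reported as
#' `NA`.
#'
#' @param values numeric vector.
#' @param labels group labels (>= 3 distinct values, each with n >= 2).
#' @return list of class `group_test_result`: test, groups, f_statistic, p,
#'   tukey (data.frame comparison/diff/padj).
#' @export
compare_multi_groups <- function(values, labels) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- factor(as.character(labels[ok]))
  groups <- levels(labels)
  if (length(groups) < 3) ribote_stop("compare_multi_groups: need >= 3 groups")
  if (any(table(labels) < 2)) ribote_stop("compare_multi_groups: every group needs n >= 2")
  if (sd(values) == 0) {
    return(structure(list(test = "anova_tukey", groups = groups,
                          f_statistic = NA_real_, p = NA_real_,
                          tukey = NULL, reason = "all values identical"),
                     class = "group_test_result"))
  }
  fit <- aov(values ~ labels)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$labels
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      padj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(test = "anova_tukey", groups = groups,
                 f_statistic = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
                 tukey = tukey),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  if (x$test == "wilcoxon") {
    cat(sprintf("Wilcoxon %s vs %s: W = %g, p = %.3g (%s)\n",
                x$groups[1], x$groups[2], x$statistic, x$p,
                if (isTRUE(x$exact)) "exact" else "normal approx."))
  } else {
    cat(sprintf("ANOVA over %d groups: F = %.3f, p = %.3g\n",
                length(x$groups), x$f_statistic, x$p))
    if (!is.null(x$tukey)) print(x$tukey)
  }
  invisible(x)
}

#' Hierarchical clustering of dTE profiles across datasets
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage via
#' `hclust(method = "ward.D2")`) of a genes x datasets matrix of log2 dTE_rel
#' values. Genes missing in one dataset are imputed as 0 (no change) and
#' flagged; alternatively dropped.
#'
#' @param mat numeric matrix, genes x datasets, with rownames.
#' @param impute_missing impute NA as 0 (TRUE, default) or drop incomplete
#'   rows (FALSE).
#' @return list of class `dte_clustering`: hclust object, leaf order (gene
#'   ids), merge heights, imputed (gene ids that had missing values), matrix
#'   used.
#' @export
cluster_delta_te <- function(mat, impute_missing = TRUE) {
  if (is.null(rownames(mat))) ribote_stop("cluster_delta_te: matrix needs rownames")
  imputed <- rownames(mat)[!complete.cases(mat)]
  if (impute_missing) {
    mat[is.na(mat)] <- 0
  } else {
    mat <- mat[complete.cases(mat), , drop = FALSE]
    imputed <- character()
  }
  if (nrow(mat) < 2) ribote_stop("cluster_delta_te: need >= 2 complete rows")
  hc <- hclust(dist(mat, method = "euclidean"), method = "ward.D2")
  structure(list(hclust = hc, leaf_order = rownames(mat)[hc$order],
                 heights = hc$height, imputed = imputed, matrix = mat),
            class = "dte_clustering")
}

#' Compare a dTE result against an external mutant's dTE table
#'
#' Pearson correlation of the shared genes' log2 dTE_rel values, plus
#' hypergeometric overlap tests of the up-regulated and down-regulated sets
#' (external calls use `|log2_dte| >= external_lfc` as the significance
#' surrogate when the external table carries no adjusted p).
#'
#' The universe is the intersection of the two tables' gene sets (genes
#' passing the expression filter in both datasets).
#'
#' @param te a `te_result` table from [test_delta_te()].
#' @param external data.frame(gene_id, log2_dte) (see [read_external_dte()]),
#'   optionally with a `padj` column.
#' @param alpha significance threshold on `te$padj` (default 0.05).
#' @param external_lfc absolute log2 threshold defining external up/down
#'   sets when no `padj` column is present (default 0.32, ~25% change).
#' @return list of class `external_comparison`: correlation
#'   (`correlation_result`), overlap_up, overlap_down (`overlap_result`),
#'   n_shared.
#' @export
compare_external <- function(te, external, alpha = 0.05,
                             external_lfc = 0.32) {
  shared <- intersect(te$gene_id, external$gene_id)
  if (length(shared) == 0) ribote_stop("compare_external: empty gene intersection")
  ti <- match(shared, te$gene_id); ei <- match(shared, external$gene_id)
  x <- te$log2_dte[ti]; y <- external$log2_dte[ei]
  corr <- correlate(x, y, method = "pearson")
  sig <- !is.na(te$padj[ti]) & te$padj[ti] < alpha
  up_a <- shared[sig & x > 0]; down_a <- shared[sig & x < 0]
  if ("padj" %in% names(external)) {
    esig <- !is.na(external$padj[ei]) & external$padj[ei] < alpha
    up_b <- shared[esig & y > 0]; down_b <- shared[esig & y < 0]
  } else {
    up_b <- shared[y >= external_lfc]; down_b <- shared[y <= -external_lfc]
  }
  structure(list(
    correlation = corr,
    overlap_up = overlap_test(up_a, up_b, shared),
    overlap_down = overlap_test(down_a, down_b, shared),
    n_shared = length(shared)
  ), class = "external_comparison")
}
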