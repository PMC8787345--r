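# Minimal base-graphics visualisations for run reports.

#' Scatter plot of dTE_rel with a correlation annotation
#' @param x,y numeric vectors (e.g. a feature vs log2 dTE_rel).
#' @param xlab,ylab axis labels.
#' @param method correlation method for the annotation.
#' @return the `correlation_result`, invisibly.
#' @export
plot_correlation <- function(x, y, xlab = "feature", ylab = "log2 dTE_rel",
                             method = "spearman") {
  cr <- correlate(x, y, method = method)
  ok <- is.finite(x) & is.finite(y)
  plot(x[ok], y[ok], pch = 16, cex = 0.4, col = "#00000055",
       xlab = xlab, ylab = ylab)
  abline(h = 0, lty = 2, col = "grey60")
  legend("topright", bty = "n", legend = sprintf(
    "%s rho = %.2f, p = %.2g (n = %d)", cr$method, cr$rho, cr$p, cr$n))
  invisible(cr)
}

#' Box plots of a feature by dTE direction
#' @param values numeric feature values.
#' @param category `te_result` categories.
#' @param ylab axis label.
#' @export
plot_feature_boxes <- function(values, category, ylab = "feature") {
  dir3 <- factor(te_direction(category), levels = c("down", "ns", "up"))
  ok <- is.finite(values) & !is.na(dir3)
  boxplot(values[ok] ~ droplevels(dir3[ok]), ylab = ylab, xlab = "dTE_rel class",
          col = c(down = "#e8c84c", ns = "white", up = "#d9543c")[
            levels(droplevels(dir3[ok]))])
}

#' Heatmap of significant dTE profiles in clustering order
#' @param clustering a `dte_clustering` from [cluster_delta_te()].
#' @export
plot_dte_heatmap <- function(clustering) {
  m <- clustering$matrix[clustering$hclust$order, , drop = FALSE]
  image(t(m), axes = FALSE, col = grDevices::hcl.colors(64, "Blue-Red 2"),
        xlab = "dataset", ylab = "genes (clustered)")
  axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m))
}

write_run_plots <- function(te, features, assoc, outdir) {
  f <- features[match(te$gene_id, features$gene_id), ]
  pdf(file.path(outdir, "report_plots.pdf"), width = 6, height = 5)
  on.exit(dev.off(), add = TRUE)
  plot_correlation(f$tl_length, te$log2_dte, xlab = "5'-UTR length (nt)")
  plot_feature_boxes(f$tl_length, te$category, ylab = "5'-UTR length (nt)")
  if (!all(is.na(f$pars_max30))) {
    plot_feature_boxes(f$pars_max30, te$category, ylab = "PARS max30")
  }
  if (!is.null(assoc$clustering)) plot_dte_heatmap(assoc$clustering)
  invisible(NULL)
}
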