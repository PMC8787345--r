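# Normalization, dispersion estimation, the NB interaction test, BH and
# fold-change classification.

test_that("size_factors match the median-of-ratios closed forms", {
  m <- matrix(rpois(400, 50) + 1L, ncol = 2)
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1]))), c(1, 1))

  sf <- size_factors(cbind(a = m[, 1], b = 2L * m[, 1]))
  expect_equal(unname(sf[2] / sf[1]), 2)

  # all-zero-free fallback
  z <- matrix(c(0L, 5L, 3L, 0L), 2)
  expect_warning(sf0 <- size_factors(z), "total-count")
  expect_equal(unname(sf0[1] / sf0[2]), 5 / 3, tolerance = 1e-12)
})

test_that("planted size factors are recovered within 5% at 2000 genes", {
  set.seed(17)
  true_sf <- c(0.5, 1, 1, 2)
  mu <- rlnorm(2000, log(200), 1)
  mat <- sapply(true_sf, function(s) rnbinom(2000, mu = mu * s, size = 1 / 0.02))
  rownames(mat) <- sprintf("g%d", 1:2000)
  colnames(mat) <- paste0(c("WT", "WT", "MUT", "MUT"), "_", c(1, 2, 1, 2))
  sf <- size_factors(mat)
  norm <- function(x) x / exp(mean(log(x)))
  expect_lt(max(abs(norm(sf) / norm(true_sf) - 1)), 0.05)
})

test_that("compute_te_rel satisfies its ratio identities", {
  pair <- simulate_pair(50, seed = 2)
  # identical normalized RP and RNA -> TE 1
  te <- compute_te_rel(pair$rna, pair$rna, sf_rp = rep(1, 4),
                       sf_rna = rep(1, 4))
  expect_true(all(te$te_WT[is.finite(te$te_WT)] == 1))

  # doubling every library's counts leaves TE_rel unchanged
  te1 <- compute_te_rel(pair$rp, pair$rna,
                        sf_rp = rep(1, 4), sf_rna = rep(1, 4))
  double_cm <- function(se, what) {
    count_matrix(2L * SummarizedExperiment::assay(se), what,
                 condition = c("WT", "WT", "MUT", "MUT"),
                 replicate = c(1, 2, 1, 2))
  }
  te2 <- compute_te_rel(double_cm(pair$rp, "RP"), double_cm(pair$rna, "RNA"),
                        sf_rp = rep(2, 4), sf_rna = rep(2, 4))
  expect_equal(te1$te_WT, te2$te_WT, tolerance = 1e-12)
  expect_equal(te1$log2_te_ratio, te2$log2_te_ratio, tolerance = 1e-12)

  # parameter recovery: true TE ratio 2 between conditions
  pair2 <- simulate_pair(200, mu_rna = 500, alpha = 0.02, log2_dte = 1,
                         seed = 3)
  te3 <- compute_te_rel(pair2$rp, pair2$rna, sf_rp = rep(1, 4),
                        sf_rna = rep(1, 4))
  expect_lt(abs(mean(te3$log2_te_ratio, na.rm = TRUE) - 1), 0.1)
})

test_that("estimate_dispersion recovers known dispersions", {
  set.seed(5)
  # Poisson counts: raw estimates concentrate at the floor
  mu <- rlnorm(500, log(150), 0.5)
  pois <- sapply(1:4, function(j) rpois(500, mu))
  rownames(pois) <- sprintf("g%d", 1:500)
  se <- tiny_rna(pois)
  d <- estimate_dispersion(se, sf = rep(1, 4))
  expect_lt(median(d$dispersion_raw), 0.02)
  expect_lt(median(d$dispersion), 0.02)

  # NB at dispersion 0.1: shrunken median inside [0.07, 0.13]
  nb <- sapply(1:4, function(j) rnbinom(500, mu = mu, size = 1 / 0.1))
  rownames(nb) <- sprintf("g%d", 1:500)
  d2 <- estimate_dispersion(tiny_rna(nb), sf = rep(1, 4))
  expect_gt(median(d2$dispersion), 0.07)
  expect_lt(median(d2$dispersion), 0.13)

  # degenerate constant gene gets the trend value and a flag
  cm <- nb; cm[1, ] <- 100L
  d3 <- estimate_dispersion(tiny_rna(cm), sf = rep(1, 4))
  expect_true(d3$degenerate[1])
  expect_equal(d3$dispersion[1], d3$dispersion_trend[1])
})

test_that("adjust_bh matches hand computation and stats::p.adjust", {
  expect_equal(adjust_bh(0.03), 0.03)  # m = 1
  # hand-computed: max over tail of p * m / rank
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))

  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  set.seed(8)
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(adjust_bh(p), stats::p.adjust(p, "BH"))
    expect_equal(adjust_bh(p), oracle_bh(p))
    # BH properties
    padj <- adjust_bh(p)
    expect_true(all(padj >= p))
    o <- order(p)
    expect_true(all(diff(padj[o]) >= -1e-15))
  }
  # NA propagation
  p <- c(0.01, NA, 0.5)
  padj <- adjust_bh(p)
  expect_true(is.na(padj[2]))
  expect_equal(padj[c(1, 3)], stats::p.adjust(p, "BH")[c(1, 3)])
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classify_te_change applies the 50%/100% fold bands under the padj gate", {
  expect_equal(classify_te_change(1.2, 0.01), "up100")   # 2^1.2 > 2
  expect_equal(classify_te_change(3, 0.2), "ns")         # not significant
  expect_equal(classify_te_change(-0.7, 0.01), "down50") # 2^-0.7 = 0.616 <= 2/3
  expect_equal(classify_te_change(log2(1.5), 0.01), "up50")  # boundary: >= 1.5
  expect_equal(classify_te_change(1, 0.01), "up100")         # boundary: ratio 2
  expect_equal(classify_te_change(-1, 0.01), "down100")
  expect_equal(classify_te_change(0.1, 0.01), "sig_small")
  expect_equal(classify_te_change(NA_real_, 0.01), "ns")
})

test_that("test_delta_te is antisymmetric under condition swap", {
  pair <- simulate_pair(60, alpha = 0.05, log2_dte = 0.8, seed = 9)
  te1 <- suppressMessages(test_delta_te(pair$rp, pair$rna))
  swap <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    cd$condition <- ifelse(cd$condition == "WT", "MUT", "WT")
    SummarizedExperiment::colData(se) <- cd
    se
  }
  te2 <- suppressMessages(test_delta_te(swap(pair$rp), swap(pair$rna)))
  ok <- !is.na(te1$log2_dte) & !is.na(te2$log2_dte)
  expect_gt(mean(ok), 0.95)
  expect_equal(te1$log2_dte[ok], -te2$log2_dte[ok], tolerance = 1e-6)
})

test_that("log2_dte converges to the plug-in estimator for large counts", {
  # oracle: plug-in log2[(RP_mut/RNA_mut)/(RP_wt/RNA_wt)] on the same counts
  pair <- simulate_pair(40, mu_rna = 1e4, alpha = 1e-6, log2_dte = 0.5,
                        seed = 10)
  te <- suppressMessages(test_delta_te(
    pair$rp, pair$rna,
    sf = list(rp = rep(1, 4), rna = rep(1, 4)),
    dispersions = list(
      rp = data.frame(gene_id = rownames(pair$rp), dispersion = 1e-8),
      rna = data.frame(gene_id = rownames(pair$rna), dispersion = 1e-8)
    )))
  rp <- SummarizedExperiment::assay(pair$rp)
  rna <- SummarizedExperiment::assay(pair$rna)
  plug <- log2((rowSums(rp[, 3:4]) / rowSums(rna[, 3:4])) /
                 (rowSums(rp[, 1:2]) / rowSums(rna[, 1:2])))
  expect_equal(te$log2_dte, unname(plug[te$gene_id]), tolerance = 0.01)
})

test_that("scaling one sample's counts is absorbed by its size factor", {
  pair <- simulate_pair(300, alpha = 0.03, seed = 12)
  te1 <- suppressMessages(test_delta_te(pair$rp, pair$rna))
  rp2 <- SummarizedExperiment::assay(pair$rp)
  rp2[, 2] <- 3L * rp2[, 2]
  scaled <- count_matrix(rp2, "RP", condition = c("WT", "WT", "MUT", "MUT"),
                         replicate = c(1, 2, 1, 2))
  te2 <- suppressMessages(test_delta_te(scaled, pair$rna))
  sf1 <- attr(te1, "size_factors")$rp
  sf2 <- attr(te2, "size_factors")$rp
  # median-of-ratios: the scaled sample's factor grows by exactly x3
  # relative to every other library
  expect_equal(unname((sf2[2] / sf2[1]) / (sf1[2] / sf1[1])), 3,
               tolerance = 1e-12)
  # the scaling is absorbed by the offsets: estimates move only through the
  # NB reweighting of the (genuinely different) counts, which vanishes in
  # the Poisson limit; at this dispersion the shift stays small
  ok <- !is.na(te1$log2_dte) & !is.na(te2$log2_dte)
  expect_lt(max(abs(te1$log2_dte[ok] - te2$log2_dte[ok])), 0.02)
  expect_equal(te1$log2_dte[ok], te2$log2_dte[ok], tolerance = 0.05)
})

test_that("genes with planted effects are recovered without material bias", {
  pair <- simulate_pair(200, mu_rna = 300, alpha = 0.02, log2_dte = -1,
                        seed = 14)
  te <- suppressMessages(test_delta_te(pair$rp, pair$rna,
                                       sf = list(rp = rep(1, 4),
                                                 rna = rep(1, 4))))
  expect_gt(attr(te, "convergence"), 0.99)
  est <- mean(te$log2_dte, na.rm = TRUE)
  expect_gt(est, -1.15)
  expect_lt(est, -0.85)
})
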