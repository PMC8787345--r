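# Association statistics against enumeration oracles and invariants.

test_that("correlate reproduces closed-form rank results", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  r <- correlate(x, y, "spearman")
  # closed form: 1 - 6 * sum(d^2) / (n (n^2 - 1)), d^2 = (1,1,1,1,0) -> 0.8
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))
  expect_equal(r$rho, 0.8)
  expect_equal(r$rho, cor(x, y, method = "spearman"))
  expect_equal(r$n, 5)
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(r$p, 2 * pt(-abs(tstat), df = 3))

  # affine invariances
  expect_equal(correlate(x, 2 * x + 1, "pearson")$rho, 1)
  expect_equal(correlate(x, exp(x), "spearman")$rho, 1)
  expect_equal(correlate(x, exp(x), "spearman")$p, 0)

  # degenerate inputs are reported as missing with a reason
  r0 <- correlate(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(r0$rho))
  expect_match(r0$reason, "zero variance")
  r1 <- correlate(c(1, 2), c(3, 4))
  expect_match(r1$reason, "fewer than 3")

  # pairwise deletion of missing values
  r2 <- correlate(c(x, NA), c(y, 100), "spearman")
  expect_equal(r2$rho, 0.8)
  expect_equal(r2$n, 5)
})

test_that("overlap_test matches exhaustive enumeration for N <= 12", {
  u <- letters[1:10]
  a <- u[1:5]; b <- u[c(1, 2, 3, 4)]
  res <- overlap_test(a, b, u)
  expect_equal(res$n_overlap, 4)
  expect_equal(res$p_hyper, 5 / 210)               # worked example
  expect_equal(res$p_hyper, oracle_hyper_p(u, a, b))

  # a = universe: overlap forced, p = 1
  expect_equal(overlap_test(u, b, u)$p_hyper, 1)

  # disjoint sets still give p in (0, 1]
  res_d <- overlap_test(u[1:3], u[4:6], u)
  expect_gt(res_d$p_hyper, 0)
  expect_lte(res_d$p_hyper, 1)
  expect_equal(res_d$p_hyper, oracle_hyper_p(u, u[1:3], u[4:6]))

  # random instances with N <= 12
  set.seed(6)
  for (rep in 1:20) {
    N <- sample(4:12, 1)
    uu <- letters[1:N]
    aa <- sample(uu, sample(1:N, 1))
    bb <- sample(uu, sample(1:N, 1))
    expect_equal(overlap_test(aa, bb, uu)$p_hyper,
                 oracle_hyper_p(uu, aa, bb), tolerance = 1e-12)
  }

  expect_error(overlap_test(c("zz"), b, u), "outside the universe")
})

test_that("overlap p never increases as the overlap grows at fixed margins", {
  # direct phyper-tail monotonicity at fixed N, |a|, |b|
  N <- 50; K <- 20; nb <- 15
  p <- vapply(0:min(K, nb), function(ov) {
    stats::phyper(ov - 1, K, N - K, nb, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p) <= 1e-15))
})

test_that("compare_two_groups matches exact enumeration and is symmetric", {
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  r <- compare_two_groups(c(g1, g2), rep(c("a", "b"), each = 3))
  expect_true(r$exact)
  expect_equal(r$p, 0.1)  # 2/20 most extreme labelings
  expect_equal(r$p, oracle_wilcoxon_p(g1, g2))

  # label swap leaves p unchanged
  r2 <- compare_two_groups(c(g2, g1), rep(c("b", "a"), each = 3))
  expect_equal(r2$p, r$p)

  # identical groups: exact p = 1
  expect_equal(compare_two_groups(c(1, 2, 7, 1, 2, 7),
                                  rep(c("a", "b"), 3))$p, 1)

  # random tie-free instances with N <= 12 against full enumeration
  set.seed(7)
  for (rep in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(seq(1, 100), n1 + n2)  # distinct -> no ties
    r3 <- compare_two_groups(v, rep(c("x", "y"), c(n1, n2)))
    expect_equal(r3$p, oracle_wilcoxon_p(v[seq_len(n1)], v[-seq_len(n1)]),
                 tolerance = 1e-12)
  }

  expect_error(compare_two_groups(1:4, rep("a", 4)), "two groups")
})

test_that("compare_multi_groups: calibration, power and equivariance", {
  # type-I: three null groups, many repetitions, ~5% rejections
  set.seed(15)
  rej <- replicate(400, {
    v <- rnorm(15)
    compare_multi_groups(v, rep(c("a", "b", "c"), each = 5))$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  # power: shifting one group by +10 SD drives its Tukey padj below 0.001
  v <- c(rnorm(6), rnorm(6), rnorm(6) + 10)
  lab <- rep(c("a", "b", "c"), each = 6)
  r <- compare_multi_groups(v, lab)
  pc <- r$tukey
  expect_lt(pc$padj[pc$comparison == "c-a"], 1e-3)
  expect_lt(pc$padj[pc$comparison == "c-b"], 1e-3)
  expect_gt(pc$padj[pc$comparison == "b-a"], 0.05)

  # permuting group order maps pairwise padj consistently
  perm <- sample(length(v))
  r2 <- compare_multi_groups(v[perm], lab[perm])
  expect_equal(sort(r2$tukey$padj), sort(r$tukey$padj), tolerance = 1e-12)
  expect_equal(r2$f_statistic, r$f_statistic)

  # all-identical data: F undefined, reported
  r3 <- compare_multi_groups(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(is.na(r3$f_statistic))
  expect_error(compare_multi_groups(rnorm(4), rep(c("a", "b"), each = 2)),
               ">= 3 groups")
})

test_that("cluster_delta_te is deterministic Ward clustering with sane heights", {
  m <- matrix(c(0, 1, 10), ncol = 1,
              dimnames = list(c("g0", "g1", "g10"), "d1"))
  cl <- cluster_delta_te(m)
  # first merge joins the two closest points (0 and 1): brute force over the
  # three possible first merges confirms 0-1 is the minimum-cost pair
  first <- cl$hclust$merge[1, ]
  expect_setequal(rownames(m)[-first], c("g0", "g1"))
  expect_true(all(diff(cl$heights) >= -1e-12))

  # identical rows merge at height 0
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  expect_equal(cluster_delta_te(m2)$heights[1], 0)

  # row permutation changes leaf order only, not merge heights
  m3 <- matrix(rnorm(40), ncol = 2,
               dimnames = list(paste0("g", 1:20), c("a", "b")))
  cl3 <- cluster_delta_te(m3)
  perm <- sample(20)
  cl4 <- cluster_delta_te(m3[perm, ])
  expect_equal(sort(cl3$heights), sort(cl4$heights), tolerance = 1e-12)
  expect_setequal(cl3$leaf_order, cl4$leaf_order)

  # missing handling: imputed-as-zero genes are flagged
  m5 <- rbind(a = c(1, NA), b = c(1, 2), c = c(5, 9))
  cl5 <- cluster_delta_te(m5)
  expect_equal(cl5$imputed, "a")
  expect_equal(unname(cl5$matrix["a", 2]), 0)
  expect_error(cluster_delta_te(m2[1, , drop = FALSE]), ">= 2")
})

test_that("compare_external recovers self, flipped and planted relationships", {
  pair <- simulate_pair(150, alpha = 0.03, log2_dte = 0.6, seed = 18)
  te <- suppressMessages(test_delta_te(pair$rp, pair$rna))
  self <- data.frame(gene_id = te$gene_id, log2_dte = te$log2_dte,
                     padj = te$padj)
  cmp <- compare_external(te, self)
  expect_equal(cmp$correlation$rho, 1)
  flip <- transform(self, log2_dte = -log2_dte)
  expect_equal(compare_external(te, flip)$correlation$rho, -1)
  expect_error(compare_external(te, data.frame(gene_id = "none",
                                               log2_dte = 1)),
               "empty gene intersection")
})

test_that("planted cross-dataset correlation is recovered", {
  # strong, dense effects so estimation noise barely attenuates the planted
  # external correlation of 0.6
  cfg <- sim_config(1200, seed = 19, frac_null = 0,
                    mean_expression_dist = list(meanlog = log(400), sdlog = 0.8),
                    effect_model = list(intercept = 0, utr_length = 0,
                                        max30 = 0, context_score = 0,
                                        sd = 0.8),
                    external_cor = 0.6)
  sim <- generate_transcriptome(cfg)
  cnt <- generate_counts(sim, cfg)
  rp <- suppressMessages(count_cds(cnt$positions, sim$annotation))
  kept <- filter_low_expression(cnt$rna)
  g <- intersect(kept, rownames(rp))
  te <- suppressMessages(test_delta_te(rp[g, ], cnt$rna[g, ]))
  ext <- generate_external_dte(sim$truth, cfg)
  cmp <- compare_external(te, ext)
  expect_gt(cmp$correlation$rho, 0.5)
  expect_lt(cmp$correlation$rho, 0.7)
  # overlap of down/down sets is strongly non-random
  expect_lt(cmp$overlap_down$p_hyper, 1e-4)
})
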