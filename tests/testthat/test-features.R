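# Feature scoring: PARS windows, Kozak PWM, logos, cap distances.

test_that("pars_window_stat matches direct slicing and brute force", {
  # constant track: every statistic equals the constant
  track <- rep(2.5, 400)
  for (w in c("utr_all", "first30", "start30", "plus30", "max30")) {
    expect_equal(pars_window_stat(track, tl_length = 100, cds_start = 100,
                                  window = w), 2.5)
  }

  # spike fixture: TL = 40, zeros except positions 5..9 (0-based) = 10
  tr <- rep(0, 400)
  tr[6:10] <- 10
  expect_equal(pars_window_stat(tr, 40, 40, "max30"), 50 / 30)
  expect_equal(pars_window_stat(tr, 40, 40, "max30"), oracle_max30(tr, 40))
  expect_equal(pars_window_stat(tr, 40, 40, "first30"), 50 / 30)
  expect_equal(pars_window_stat(tr, 40, 40, "utr_all"), 50 / 40)
  # start30 = mean over [25, 55), which contains no spike
  expect_equal(pars_window_stat(tr, 40, 40, "start30"), 0)

  # containment: TL = 29 -> first30 and max30 missing
  expect_true(is.na(pars_window_stat(tr, 29, 29, "first30")))
  expect_true(is.na(pars_window_stat(tr, 29, 29, "max30")))
  # start30 needs 15 nt upstream: cds_start = 10 -> missing
  expect_true(is.na(pars_window_stat(tr, 10, 10, "start30")))
  # plus30 running past the transcript end -> missing
  expect_true(is.na(pars_window_stat(rep(1, 50), 10, 10, "plus30")))

  # missing values inside a window propagate
  tr2 <- rep(1, 100); tr2[20] <- NA
  expect_true(is.na(pars_window_stat(tr2, 60, 60, "utr_all")))
  expect_true(is.na(pars_window_stat(tr2, 60, 60, "first30")))
  expect_equal(pars_window_stat(tr2, 60, 60, "max30"), 1)  # complete windows exist
})

test_that("max30 equals the brute-force scan on random tracks", {
  set.seed(4)
  for (rep in 1:50) {
    tl <- sample(30:300, 1)
    track <- rnorm(tl + 50)
    expect_equal(pars_window_stat(track, tl, tl, "max30"),
                 oracle_max30(track, tl))
  }
  # and dominates every individual window mean (in particular first30)
  for (rep in 1:20) {
    tl <- sample(30:120, 1)
    track <- rnorm(tl + 10)
    m <- pars_window_stat(track, tl, tl, "max30")
    expect_gte(m, pars_window_stat(track, tl, tl, "first30"))
    i <- sample(0:(tl - 30), 1)
    expect_gte(m + 1e-12, mean(track[(i + 1):(i + 30)]))
  }
})

test_that("context PWM scoring behaves as a log-odds model", {
  # all inputs identical: that window achieves the maximal possible score
  win <- "TTCGAAATGC"
  pwm <- build_context_pwm(rep(win, 20))
  s_self <- context_score(win, pwm)
  set.seed(2)
  others <- replicate(200, paste0(
    paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""), "ATG",
    sample(c("A", "C", "G", "T"), 1)))
  expect_true(all(context_score(others, pwm) <= s_self + 1e-12))

  # uniform random inputs at large n: scores concentrate near 0
  set.seed(3)
  unif <- replicate(2000, paste0(
    paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""), "ATG",
    sample(c("A", "C", "G", "T"), 1)))
  pwm_u <- build_context_pwm(unif)
  expect_lt(abs(mean(context_score(unif[1:500], pwm_u))), 0.35)

  # pseudocount: a base absent at a position still has finite weight
  pwm_a <- build_context_pwm(rep("AAAAAAATGA", 10))
  expect_true(all(is.finite(pwm_a$log_odds)))
  expect_true(is.finite(context_score("CCCCCCATGC", pwm_a)))

  # non-AUG cores are rejected with a warning
  expect_warning(build_context_pwm(c(win, "TTCGAATTGC")), "AUG core")

  # monotonicity: enriching A at -3 raises the score of the A variant
  a_rich <- c(rep("TTTATTATGC", 8), "TTTTTTATGC")
  pwm_m <- build_context_pwm(a_rich)
  expect_gt(context_score("TTTATTATGC", pwm_m),
            context_score("TTTTTTATGC", pwm_m))
})

test_that("consensus window is maximal over the full 4^7 enumeration", {
  set.seed(11)
  sim <- generate_transcriptome(sim_config(120, seed = 11))
  wins <- context_windows(sim$sequences, sim$annotation)
  pwm <- build_context_pwm(wins)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), 7), stringsAsFactors = FALSE)
  all_windows <- apply(grid, 1, function(g) {
    paste0(paste(g[1:6], collapse = ""), "ATG", g[7])
  })
  scores <- context_score(all_windows, pwm)
  # per-position argmax must reach the enumerated maximum
  lo <- pwm$log_odds
  best <- paste0(
    paste(bases[apply(lo[, 1:6], 2, which.max)], collapse = ""), "ATG",
    bases[which.max(lo[, 10])])
  expect_equal(unname(context_score(best, pwm)), max(scores))
  # against the self-universe background, upstream positions are only as
  # informative as their composition deviates from the pooled background;
  # the +4 consensus G (scored against the A-rich upstream background) must
  # carry a strongly positive weight, and swapping +4 G for any other base
  # always lowers the score by that weight difference
  expect_gt(pwm$log_odds["G", "p4"], 1)
  expect_equal(unname(context_score("AAAAAAATGG", pwm) -
                        context_score("AAAAAAATGA", pwm)),
               unname(pwm$log_odds["G", "p4"] - pwm$log_odds["A", "p4"]))
})

test_that("context windows respect the TL >= 6 boundary", {
  tr <- data.frame(gene_id = c("g1", "g2"), transcript_id = c("t1", "t2"),
                   tx_length = c(50L, 50L), tl_length = c(5L, 6L),
                   cds_start = c(5L, 6L), cds_length = c(30L, 30L))
  ann <- annotation_set(tr)
  seqs <- Biostrings::DNAStringSet(c(
    t1 = paste(rep("A", 50), collapse = ""),
    t2 = paste0("CCCCCC", "ATG", "G", paste(rep("A", 40), collapse = ""))))
  w <- context_windows(seqs, ann)
  expect_true(is.na(w[["t1"]]))  # tl 5 < 6 -> missing
  expect_equal(w[["t2"]], "CCCCCCATGG")

  # length mismatch between sequence and annotation is a hard error
  seqs_bad <- Biostrings::DNAStringSet(c(t1 = "ACGT", t2 = as.character(seqs[[2]])))
  expect_error(context_windows(seqs_bad, ann), "mismatch")
})

test_that("sequence_logo_matrix computes entropy-based information content", {
  # single base at every position: 2 bits
  lm1 <- sequence_logo_matrix(rep("AAAAAAATGG", 5))
  expect_equal(unname(lm1$ic), rep(2, 10))
  # uniform usage: 0 bits
  lm2 <- sequence_logo_matrix(c("AAAAAAATGA", "CCCCCCATGC",
                                "GGGGGGATGG", "TTTTTTATGT"))
  expect_equal(unname(lm2$ic[c(1:6, 10)]), rep(0, 7))
  # p = (0.5, 0.5, 0, 0): 1 bit
  lm3 <- sequence_logo_matrix(c("AAAAAAATGA", "CCCCCCATGA"))
  expect_equal(unname(lm3$ic[1]), 1)
  expect_true(all(lm3$ic >= 0 & lm3$ic <= 2))
  expect_error(sequence_logo_matrix(character()), "empty")
})

test_that("uorf_cap_distance returns 5' offsets in annotation order", {
  uorfs <- data.frame(
    gene_id = c("gene1", "gene1"), transcript_id = c("gene1_t1", "gene1_t1"),
    uorf_id = c("u1", "u2"), start = c(0L, 120L), length = c(9L, 12L),
    start_codon = c("ATG", "TTG"), stringsAsFactors = FALSE)
  ann <- tiny_annotation(tl = 200L, cds_codons = 50L, uorfs = uorfs)
  cd <- uorf_cap_distance(ann)
  expect_equal(cd$cap_distance, c(0L, 120L))
  expect_equal(cd$uorf_id, c("u1", "u2"))
})

test_that("build_feature_table assembles per-gene features coherently", {
  cfg <- sim_config(60, seed = 13)
  sim <- generate_transcriptome(cfg)
  ft <- build_feature_table(sim$annotation, sim$sequences, sim$pars,
                            isoforms = sim$isoforms,
                            closed_loop = sim$closed_loop)
  expect_equal(nrow(ft), 60)
  # TL length present exactly for dominant-isoform genes
  expect_equal(!is.na(ft$tl_length),
               sim$truth$dominant[match(ft$gene_id, sim$truth$gene_id)])
  # pars_max30 >= pars_first30 whenever both are defined
  both <- !is.na(ft$pars_max30) & !is.na(ft$pars_first30)
  expect_true(all(ft$pars_max30[both] >= ft$pars_first30[both] - 1e-12))
  # max30 agrees with the generator's planted value on the modelled TL
  expect_equal(ft$pars_max30,
               sim$truth$pars_max30_true[match(ft$gene_id, sim$truth$gene_id)])
})
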