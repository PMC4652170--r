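# chromatin_state: per-sample calls, >70% consensus, QC and Fig-1 style
# comparisons

test_that("call_sample_state maps mark combinations to states", {
  expect_equal(call_sample_state(c(TRUE, TRUE, FALSE, FALSE),
                                 c(TRUE, FALSE, TRUE, FALSE)),
               c("BIVALENT", "ACTIVE", "REPRESSED", "LATENT"))
})

test_that("consensus_threshold reproduces the strict >70% cutoffs", {
  expect_identical(consensus_threshold(11), 8L)   # eight or more of 11
  expect_identical(consensus_threshold(8), 6L)    # six or more of 8
  expect_identical(consensus_threshold(10), 8L)   # 7/10 is not > 0.7
  expect_identical(consensus_threshold(1), 1L)
  expect_error(consensus_threshold(10, fraction = 0), "fraction")
  expect_error(consensus_threshold(10, fraction = 1.2), "fraction")
})

test_that("consensus_classify applies the threshold per promoter", {
  states <- matrix("LATENT", 3, 11)
  states[1, 1:8] <- "BIVALENT"                  # 8/11 -> HC
  states[2, 1:7] <- "BIVALENT"; states[2, 8:11] <- "ACTIVE"  # 7 and 4 -> none
  sm <- make_state_matrix(states)
  cls <- consensus_classify(sm)
  expect_equal(cls$class, c("HC_BIVALENT", "UNCLASSIFIED", "HC_LATENT"))
  expect_equal(cls$n_bivalent[2], 7)
  expect_equal(cls$n_active[2], 4)
})

test_that("consensus_classify matches the brute-force recount oracle", {
  for (seed in c(11, 12)) {
    sm <- random_state_matrix(400, sample(5:12, 1), seed)
    got <- consensus_classify(sm)
    expect_equal(got$class, oracle_consensus(sm))
    # uniqueness: counts can never put two states above 50%
    hc <- got[, c("n_bivalent", "n_active", "n_repressed", "n_latent")]
    expect_true(all(rowSums(hc >= consensus_threshold(length(sm$sample_ids))) <= 1))
  }
})

test_that("HC membership is monotone in a state's sample count", {
  sm <- random_state_matrix(100, 9, 21)
  cls <- consensus_classify(sm)
  # flip one non-bivalent cell to BIVALENT; bivalent count never decreases
  # and promoters already HC_BIVALENT stay HC_BIVALENT
  sm2 <- sm
  for (i in seq_len(100)) {
    j <- which(sm$states[i, ] != "BIVALENT")[1]
    if (!is.na(j)) sm2$states[i, j] <- "BIVALENT"
  }
  cls2 <- consensus_classify(sm2)
  expect_true(all(cls2$n_bivalent >= cls$n_bivalent))
  was_hc <- cls$class == "HC_BIVALENT"
  expect_true(all(cls2$class[was_hc] == "HC_BIVALENT"))
})

test_that("detection_curve matches hand counts and the recount oracle", {
  states <- matrix("LATENT", 4, 3)
  states[1, 1:3] <- "BIVALENT"
  states[2, 1:2] <- "BIVALENT"
  states[3, 1] <- "BIVALENT"
  sm <- make_state_matrix(states)
  expect_equal(detection_curve(sm, "BIVALENT"), c(3L, 2L, 1L))
  all_biv <- make_state_matrix(matrix("BIVALENT", 5, 4))
  expect_equal(detection_curve(all_biv, "BIVALENT"), rep(5L, 4))
  sm2 <- random_state_matrix(200, 8, 31)
  for (s in c("BIVALENT", "ACTIVE", "REPRESSED", "LATENT")) {
    curve <- detection_curve(sm2, s)
    expect_equal(curve, oracle_detection_curve(sm2, s))
    expect_true(all(diff(curve) <= 0))
  }
})

test_that("top_signal_overlap ranks by score with id tie-breaks", {
  scores <- c(a = 10, b = 9, c = 8, d = 1)
  expect_equal(top_signal_overlap(scores, c("a", "b", "c")), 1.0)
  scores2 <- c(a = 10, b = 2, c = 9, d = 1)
  expect_equal(top_signal_overlap(scores2, c("a", "b")), 0.5)
  # ties broken by promoter id ascending: top-1 of equal scores is "a"
  tied <- c(b = 5, a = 5, c = 0)
  expect_equal(top_signal_overlap(tied, "a"), 1.0)
  expect_equal(top_signal_overlap(tied, "b"), 0.0)
  expect_error(top_signal_overlap(scores, character(0)), "non-empty")
  expect_error(top_signal_overlap(c(a = 1), c("a", "b")), "larger")
})

test_that("promoter_signal_scores sums scores with bp fallback", {
  prom <- promoter_windows(make_tss(c(10000, 30000), c("+", "+")))
  pk <- make_peaks("chr1", c(9500, 10100, 25000), c(9600, 10300, 25100),
                   score = c(2, 3, 5), mark = "H3K27me3")
  expect_equal(unname(promoter_signal_scores(prom, pk)), c(5, 0))
  pk_ns <- make_peaks("chr1", c(8500, 11900), c(9600, 12500))
  # overlapped bp: [9000,9600) = 600 and [11900,12000) = 100
  expect_equal(unname(promoter_signal_scores(prom, pk_ns))[1], 700)
})

test_that("mark_colocation_fraction counts co-located peak pairs", {
  prom <- promoter_windows(make_tss(c(1000, 20000, 40000, 60000),
                                    rep("+", 4)))
  k4 <- make_peaks("chr1", c(100, 19100, 39100, 59100),
                   c(200, 19300, 39200, 59400))
  k27 <- make_peaks("chr1", c(150, 19400, 39150, 59600),
                    c(400, 19600, 39300, 59700), mark = "H3K27me3")
  # promoters 1, 3 co-located; 2, 4 have both marks but disjoint peaks
  expect_equal(mark_colocation_fraction(k4, k27, prom), 0.5)
  expect_equal(mark_colocation_fraction(k4, k27, prom[c(1, 2, 3), ]), 2 / 3)
})

test_that("sample_qc computes cross-sample summaries", {
  states <- cbind(c(rep("ACTIVE", 18000), rep("LATENT", 2000)),
                  c(rep("ACTIVE", 19000), rep("LATENT", 1000)))
  sm <- make_state_matrix(states)
  qc <- sample_qc(sm)
  act <- qc$summary[qc$summary$state == "ACTIVE", ]
  expect_equal(act$mean, 18500)
  expect_equal(act$sd, 707.1068, tolerance = 1e-6)
  expect_equal(act$relative_sd_pct, 3.8222, tolerance = 1e-4)
  biv <- qc$summary[qc$summary$state == "BIVALENT", ]
  expect_true(is.na(biv$relative_sd_pct))          # mean 0 -> undefined
  expect_equal(colSums(qc$counts), c(S01 = 20000L, S02 = 20000L))
  # identical counts -> relative SD 0; depths proportional to counts -> r = 1
  sm2 <- make_state_matrix(cbind(rep("ACTIVE", 50), rep("ACTIVE", 50)))
  expect_equal(sample_qc(sm2)$summary$relative_sd_pct[2], 0)
  qc3 <- sample_qc(sm, read_depths = c(18000, 19000) * 3)
  expect_equal(qc3$summary$depth_cor[qc3$summary$state == "ACTIVE"], 1)
  expect_error(sample_qc(make_state_matrix(matrix("ACTIVE", 5, 1))), ">= 2")
})

test_that("build_state_matrix wires overlap calls per sample", {
  prom <- promoter_windows(make_tss(c(10000, 30000), c("+", "-")))
  s1 <- list(sample_id = "S01",
             k4 = make_peaks("chr1", 9900, 10100),
             k27 = make_peaks("chr1", c(9950, 29000), c(10050, 29500),
                              mark = "H3K27me3"))
  s2 <- list(sample_id = "S02",
             k4 = make_peaks("chr1", 29900, 30100),
             k27 = make_peaks("chr2", 9900, 10100, mark = "H3K27me3"))
  sm <- build_state_matrix(prom, list(s1, s2))
  expect_equal(unname(sm$states[, "S01"]), c("BIVALENT", "REPRESSED"))
  expect_equal(unname(sm$states[, "S02"]), c("LATENT", "ACTIVE"))
})
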