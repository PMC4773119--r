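m <- default_pairing_matrix()

test_that("default matrix carries the canonical duplex scores", {
  expect_identical(pair_score(m, "G", "C"), 4L)
  expect_identical(pair_score(m, "A", "T"), 2L)
  expect_identical(pair_score(m, "G", "T"), 1L)
  expect_identical(pair_score(m, "A", "C"), -6L)
  expect_identical(pair_score(m, "C", "C"), -6L)
  expect_identical(pair_score(m, "N", "G"), -6L)
  expect_identical(m$gap_open, -20L)
  expect_identical(m$gap_extend, -8L)
})

test_that("pair_score is symmetric over the whole alphabet", {
  b <- c("A", "C", "G", "T", "N")
  for (x in b) for (y in b)
    expect_identical(pair_score(m, x, y), pair_score(m, y, x))
  expect_error(pair_score(m, "X", "A"), "non-alphabet")
})

test_that("alignment_score reproduces hand-computed cases", {
  expect_identical(alignment_score(m, rbind(rep("G", 27), rep("C", 27))),
                   108L)
  expect_identical(
    alignment_score(m, rbind(c("G", "G", "G", "A", "A", "A"),
                             c("C", "C", "C", "T", "T", "T"))), 18L)
  # ten G:C columns with one length-1 gap: 40 - 28 = 12
  cols <- rbind(c(rep("G", 5), "-", rep("G", 5)),
                c(rep("C", 5), "A", rep("C", 5)))
  expect_identical(alignment_score(m, cols), 12L)
  # gap run of length 3 costs -20 - 3*8 = -44
  cols3 <- rbind(c(rep("G", 5), "-", "-", "-", rep("G", 5)),
                 c(rep("C", 5), "A", "C", "A", rep("C", 5)))
  expect_identical(alignment_score(m, cols3), 40L - 44L)
  expect_error(alignment_score(m, rbind(c("G", "-"), c("C", "-"))),
               "two gaps")
})

test_that("alignment_score is additive over blocks joined by base columns", {
  set.seed(1)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    blk <- function(n) rbind(sample(c("A", "C", "G", "T"), n, TRUE),
                             sample(c("A", "C", "G", "T"), n, TRUE))
    a <- blk(n1); b <- blk(n2)
    expect_identical(alignment_score(m, cbind(a, b)),
                     alignment_score(m, a) + alignment_score(m, b))
  }
})

test_that("threshold_from_fit inverts the Gumbel expectation", {
  fit <- list(lambda = 1, K = 0.1)
  expect_identical(threshold_from_fit(fit, target = 1, m = 1000, n = 1000),
                   12L)
  # huge target drives the threshold to the positive-score floor
  expect_identical(threshold_from_fit(fit, target = 1e6, m = 1000,
                                      n = 1000), 1L)
  # expectation at the returned threshold is below target, one less is not
  thr <- threshold_from_fit(fit, 1, 1000, 1000)
  expect_lt(expected_alignments(fit, thr, 1000, 1000), 1)
  expect_gte(expected_alignments(fit, thr - 1L, 1000, 1000), 1)
})

test_that("calibration is deterministic and monotone in the target", {
  f1 <- calibrate_threshold(m, 1e5, 1e5, target = 1, n_null_pairs = 60,
                            null_len = 300, seed = 4)
  f2 <- calibrate_threshold(m, 1e5, 1e5, target = 1, n_null_pairs = 60,
                            null_len = 300, seed = 4)
  expect_identical(f1$threshold, f2$threshold)
  expect_identical(f1$scores, f2$scores)
  stricter <- threshold_from_fit(f1, target = 0.1)
  looser <- threshold_from_fit(f1, target = 10)
  expect_gte(stricter, f1$threshold)
  expect_lte(looser, f1$threshold)
})

test_that("calibration accepts composition-preserving shuffles of a pool", {
  set.seed(2)
  pool <- vapply(1:20, function(i) rnd_seq(300, gc = 0.6), "")
  f <- calibrate_threshold(m, 1e5, 1e5, null_seqs = pool,
                           n_null_pairs = 40, seed = 9)
  expect_gt(f$lambda, 0)
  expect_gt(f$K, 0)
  expect_true(f$threshold >= 1L)
})

test_that("degenerate nulls are rejected", {
  expect_error(
    calibrate_threshold(m, 1e4, 1e4, null_seqs = rep("AAAAAAAAAA", 5),
                        n_null_pairs = 30, seed = 1),
    "degenerate")
})
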