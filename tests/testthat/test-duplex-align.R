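m <- default_pairing_matrix()

test_that("the only gapless duplex of GGGAAA vs TTTCCC is found", {
  a <- align_duplex_exact(c(q = "GGGAAA"), c(t = "TTTCCC"), m,
                          min_score = 10)
  expect_length(a, 1)
  expect_identical(a[[1]]$score, 18L)
  expect_identical(c(a[[1]]$lnc_start, a[[1]]$lnc_end), c(0L, 6L))
  expect_identical(c(a[[1]]$target_start, a[[1]]$target_end), c(0L, 6L))
})

test_that("a perfect 27-mer G:C duplex clears the mature threshold", {
  q <- strrep("G", 27)
  t <- strrep("C", 27)
  a <- align_duplex_exact(q, t, m, min_score = 107)
  expect_length(a, 1)
  expect_identical(a[[1]]$score, 108L)
})

test_that("unpairable sequences yield no alignment", {
  expect_length(align_duplex_exact(strrep("A", 30), strrep("A", 30), m, 1),
                0)
})

test_that("empty sequences and bad thresholds are rejected", {
  expect_error(align_duplex_exact("", "ACGT", m, 10), "non-empty")
  expect_error(align_duplex_exact("ACGT", "ACGT", m, 0), "min_score")
  expect_error(align_duplex_seeded("ACGT", "ACGT", m, 10, seed_score = 1),
               "seed_score")
})

test_that("planted duplex in 1-kb flanks is recovered identically by
           seeded and exact search", {
  set.seed(21)
  p <- plant_pair(1000, 1000, len = 40, lpos = 300, ws = 500, gc = 0.7)
  s <- align_duplex_seeded(c(lnc = p$lnc), c(tgt = p$target), m,
                           min_score = 107)
  e <- align_duplex_exact(c(lnc = p$lnc), c(tgt = p$target), m,
                          min_score = 107)
  expect_gte(length(s), 1)
  expect_same_alignments(s, e)
  # planted window is inside the reported hit
  expect_lte(s[[1]]$target_start, 500L)
  expect_gte(s[[1]]$target_end, 540L)
})

test_that("re-running identical input gives identical output ordering", {
  set.seed(3)
  p <- plant_pair(600, 600, 30, 100, 200)
  a1 <- align_duplex_seeded(p$lnc, p$target, m, min_score = 60)
  a2 <- align_duplex_seeded(p$lnc, p$target, m, min_score = 60)
  expect_identical(a1, a2)
})

test_that("reported scores recompute from columns and match an
           independent local-alignment oracle", {
  set.seed(8)
  for (i in 1:15) {
    q <- rnd_seq(200, gc = sample(c(0.3, 0.5, 0.7), 1))
    t <- rnd_seq(200, gc = sample(c(0.3, 0.5, 0.7), 1))
    a <- align_duplex_exact(q, t, m, min_score = 10)
    for (h in a)
      expect_identical(alignment_score(m, h), h$score)
    if (length(a)) {
      best <- max(vapply(a, `[[`, 0L, "score"))
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q),
        Biostrings::reverse(Biostrings::DNAString(t)),
        type = "local", substitutionMatrix = m$scores[1:4, 1:4],
        gapOpening = 20, gapExtension = 8)
      expect_identical(best, as.integer(Biostrings::score(pa)))
    }
  }
})

test_that("duplex symmetry: swapping roles preserves the optimum and,
           for well-separated duplexes, the full pairing set", {
  set.seed(13)
  # the optimal duplex score is role-symmetric on arbitrary inputs
  for (i in 1:10) {
    q <- rnd_seq(150)
    t <- rnd_seq(150)
    a <- align_duplex_exact(q, t, m, min_score = 12)
    b <- align_duplex_exact(t, q, m, min_score = 12)
    best <- function(x) if (length(x)) max(vapply(x, `[[`, 0L, "score"))
                        else 0L
    expect_identical(best(a), best(b))
  }
  # with unambiguous planted duplexes (unpairable poly-A background, so
  # no tie-shaped extensions exist) the whole set of
  # (score, paired-interval) tuples is symmetric
  for (i in 1:5) {
    lnc <- strrep("A", 800)
    target <- strrep("A", 800)
    w1 <- rnd_seq(30, gc = 0.7)
    w2 <- rnd_seq(30, gc = 0.7)
    substr(target, 501, 530) <- w1
    substr(lnc, 101, 130) <- revcomp(w1)
    substr(target, 101, 130) <- w2
    substr(lnc, 601, 630) <- revcomp(w2)
    a <- align_duplex_exact(lnc, target, m, min_score = 90)
    b <- align_duplex_exact(target, lnc, m, min_score = 90)
    da <- alignments_df(a)
    db <- alignments_df(b)
    expect_identical(sort(da$score), sort(db$score))
    key_a <- sort(paste(da$lnc_start, da$lnc_end, da$target_start,
                        da$target_end))
    key_b <- sort(paste(db$target_start, db$target_end, db$lnc_start,
                        db$lnc_end))
    expect_identical(key_a, key_b)
  }
})

test_that("every exact alignment above the separator bound contains a
           complementary run scoring at least the seed score", {
  # the completeness property behind the seeded search
  set.seed(17)
  seed_needed <- min(-m$mismatch, -(m$gap_open + m$gap_extend)) + 1L
  expect_identical(seed_needed, 7L)
  for (i in 1:30) {
    q <- rnd_seq(120)
    t <- rnd_seq(120)
    for (h in align_duplex_exact(q, t, m, min_score = seed_needed)) {
      cols <- alignment_columns(h)
      sc <- ifelse(cols[1, ] == "-" | cols[2, ] == "-", -99L,
                   pair_score(m, cols[1, ], cols[2, ]))
      run <- 0L
      best_run <- 0L
      for (s in sc) {
        run <- if (s > 0) run + s else 0L
        best_run <- max(best_run, run)
      }
      expect_gte(best_run, seed_needed)
    }
  }
})

test_that("alignments never extend through long N runs", {
  set.seed(30)
  lnc <- rnd_seq(300)
  left <- rnd_seq(100, gc = 0.7)
  right <- rnd_seq(100, gc = 0.7)
  target <- paste0(left, strrep("N", 50), right)
  for (h in align_duplex_exact(lnc, target, m, min_score = 20)) {
    cols <- alignment_columns(h)
    n_run <- rle(cols[2, ] == "N")
    expect_true(all(n_run$lengths[n_run$values] < 20 / 6 + 1))
  }
})

test_that("search_transcriptome unions per-pair hits with stable order", {
  set.seed(44)
  p <- plant_pair(500, 500, 35, 100, 200, gc = 0.7)
  lncs <- c(lncA = p$lnc, lncB = rnd_seq(500))
  targets <- c(tA = p$target, tB = rnd_seq(500))
  hits <- search_transcriptome(lncs, targets, m, min_score = 107)
  expect_length(hits, 1)
  expect_identical(hits[[1]]$lnc_id, "lncA")
  expect_identical(hits[[1]]$target_id, "tA")
  expect_error(search_transcriptome(character(), targets, m, 107), "empty")
  expect_error(search_transcriptome(c(tA = "ACGT"), targets, m, 107),
               "collision")
})
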