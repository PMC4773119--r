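fx <- make_fixture(seed = 7)
m <- default_pairing_matrix()

test_that("fixture generation is deterministic and respects closed-form
           truth scores", {
  fx2 <- make_fixture(seed = 7)
  expect_identical(fx[names(fx) != "seed"], fx2[names(fx2) != "seed"])
  cfg <- fx$config
  # planted score by composition: 4*GC + 2*AT
  expect_true(all(fx$truth$duplexes$score[-1] ==
                    4L * cfg$plant_gc +
                    2L * (cfg$plant_len - cfg$plant_gc)))
  # a different seed changes the genome but not the design
  fx3 <- make_fixture(seed = 8)
  expect_false(identical(fx3$genome, fx$genome))
  expect_identical(fx3$truth$regulatory, fx$truth$regulatory)
})

test_that("written fixture bundles are byte-identical for one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(make_fixture(seed = 5), d1)
  write_fixture(make_fixture(seed = 5), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("all planted duplexes at or above threshold are recovered at
           exact coordinates and scores, with no extra hits", {
  d <- fx$truth$duplexes
  alns <- search_transcriptome(fx$lnc, fx$targets, m, 107, mode = "mRNA")
  got <- alignments_df(alns)
  got <- got[order(got$lnc_id, got$target_start), ]
  exp <- d[d$in_mrna, ]
  exp <- exp[order(exp$lnc_id, exp$tx_start), ]
  expect_identical(nrow(got), nrow(exp))
  expect_identical(got$lnc_id, exp$lnc_id)
  expect_identical(got$target_id, exp$target_id)
  expect_identical(got$lnc_start, exp$lnc_start)
  expect_identical(got$lnc_end, exp$lnc_end)
  expect_identical(got$target_start, exp$tx_start)
  expect_identical(got$target_end, exp$tx_end)
  expect_identical(got$score, exp$score)
})

test_that("planted truth survives a full pipeline truth check", {
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  alns_m <- search_transcriptome(fx$lnc, fx$targets, m, 107, mode = "mRNA")
  ints_m <- annotate_interactions(alns_m, fx$models, fx$lnc_models)
  queries <- lapply(fx$models, build_premrna_query, genome = fx$genome)
  qseqs <- setNames(vapply(queries, `[[`, "", "seq"), names(queries))
  alns_p <- search_transcriptome(fx$lnc, qseqs, m, 108, mode = "pre-mRNA")
  jn <- Filter(function(a) spans_junction(a, queries[[a$target_id]]),
               alns_p)
  ints_p <- annotate_interactions(jn, fx$models, fx$lnc_models)
  reg <- regulatory_annotations(ints_m, ints_p, fx$features,
                                c(fx$models, fx$lnc_models))
  gene_map <- vapply(c(fx$models, fx$lnc_models), `[[`, "", "gene_id")
  counts <- filter_unique(fx$mappings, "transcript", gene_map)
  lens <- vapply(c(fx$models, fx$lnc_models), tx_length, 0L)
  tab <- expression_table(counts, lens)
  results <- list(mrna_alignments = alns_m, premrna_alignments = alns_p,
                  junction_alignments = jn, regulatory = reg,
                  coexpression = coexpression_report(c(ints_m, ints_p),
                                                     tab))
  chk <- truth_check(results, fx$truth)
  expect_true(chk$pass)
  # missing stage output errors
  expect_error(truth_check(results[-1], fx$truth), "missing stage")
})

test_that("each single-feature perturbation moves exactly one count by
           one", {
  run_counts <- function(f) {
    alns_m <- search_transcriptome(f$lnc, f$targets, m, 107,
                                   mode = "mRNA")
    ints_m <- annotate_interactions(alns_m, f$models, f$lnc_models)
    queries <- lapply(f$models, build_premrna_query, genome = f$genome)
    qseqs <- setNames(vapply(queries, `[[`, "", "seq"), names(queries))
    alns_p <- search_transcriptome(f$lnc, qseqs, m, 108,
                                   mode = "pre-mRNA")
    jn <- Filter(function(a) spans_junction(a, queries[[a$target_id]]),
                 alns_p)
    ints_p <- annotate_interactions(jn, f$models, f$lnc_models)
    ann <- regulatory_annotations(ints_m, ints_p, f$features,
                                  c(f$models, f$lnc_models))
    vapply(c("splice_mask", "mirna_mask", "smd", "editing"),
           function(x) sum(ann$mechanism == x), 0L)
  }
  base <- run_counts(fx)
  expect_identical(unname(base), rep(1L, 4))
  hit_of <- c(alu = "smd", mirna = "mirna_mask", clip = "splice_mask",
              editing = "editing")
  for (w in names(hit_of)) {
    pert <- run_counts(perturb_fixture(fx, w))
    delta <- base - pert
    expect_identical(unname(delta[hit_of[[w]]]), 1L, label = w)
    expect_identical(sum(delta), 1L, label = w)
  }
})

test_that("planted-duplex longer than its host errors", {
  cfg <- fixture_config()
  cfg$plant_len <- cfg$lnc_len + 1L
  expect_error(make_fixture(cfg, seed = 1), "longer than host")
})
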