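# hand-built interaction over a single-exon protein-coding target:
# genomic target region = [g_start + s, g_start + e) on "+"
mk_interaction <- function(s, e, mode = "mRNA", strand = "+",
                           biotype = "protein_coding",
                           exon = c(1000L, 2000L), cds = c(1120L, 1800L)) {
  tm <- toy_model(strand = strand,
                  exons = data.frame(start = exon[1], end = exon[2]),
                  cds = if (biotype == "protein_coding") cds else NULL,
                  biotype = biotype, id = "tgt", gene = "gt")
  lm <- toy_model(strand = "+",
                  exons = data.frame(start = 5000L, end = 5400L),
                  biotype = "noncoding", id = "lnc", gene = "gl")
  a <- duplex_alignment("lnc", "tgt", 0L, e - s, s, e, 120L,
                        strrep("G", e - s), strrep("C", e - s),
                        400L, if (mode == "mRNA") tx_length(tm)
                              else premrna_length(tm), mode)
  annotate_interactions(list(a), list(tgt = tm), list(lnc = lm))[[1]]
}

test_that("splice-signal masking needs full containment on the same strand", {
  # pre-mRNA target with an intron: exons [0,100) [700,800), junction 100
  tm <- toy_model(exons = data.frame(start = c(0L, 700L),
                                     end = c(100L, 800L)),
                  cds = NULL, biotype = "noncoding", id = "tgt",
                  gene = "gt")
  lm <- toy_model(exons = data.frame(start = 5000L, end = 5400L),
                  biotype = "noncoding", id = "lnc", gene = "gl")
  a <- duplex_alignment("lnc", "tgt", 0L, 100L, 50L, 150L, 120L,
                        strrep("G", 100), strrep("C", 100), 400L,
                        premrna_length(tm), "pre-mRNA")
  rec <- annotate_interactions(list(a), list(tgt = tm),
                               list(lnc = lm))[[1]]
  models <- list(tgt = tm, lnc = lm)
  inside <- bed("chr1", 120L, 140L, name = "c1")          # region [50,150)
  partial <- bed("chr1", 40L, 140L, name = "c2")
  wrong_strand <- bed("chr1", 120L, 140L, name = "c3", strand = "-")
  out <- splice_mask_candidates(list(rec),
                                rbind(inside, partial, wrong_strand),
                                models)
  expect_identical(nrow(out), 1L)
  expect_identical(out$evidence_start, 120L)
  expect_identical(out$splice_site_class, "constitutive")
})

test_that("splice-site classification distinguishes isoform usage", {
  ex_a <- data.frame(start = c(0L, 300L, 700L), end = c(100L, 400L, 800L))
  ex_b <- data.frame(start = c(0L, 700L), end = c(100L, 800L))
  ta <- transcript_model("ta", "g", "chr1", "+", ex_a, NULL, "noncoding")
  tb <- transcript_model("tb", "g", "chr1", "+", ex_b, NULL, "noncoding")
  models <- list(ta = ta, tb = tb)
  expect_identical(classify_splice_site(models, "chr1", 300L),
                   "alternative")   # used by ta only, tb covers it
  expect_identical(classify_splice_site(models, "chr1", 100L),
                   "constitutive")  # used by both
  expect_identical(classify_splice_site(list(ta = ta), "chr1", 300L),
                   "constitutive")  # single isoform: vacuously used by all
  expect_error(classify_splice_site(models, "chr1", 55L),
               "not an exon boundary")
})

test_that("miRNA masking keeps sites with at least half inside", {
  rec <- mk_interaction(100L, 200L)  # genomic region [1100, 1200)
  site8 <- function(s) bed("chr1", s, s + 8L)
  expect_identical(nrow(mirna_mask_candidates(list(rec), site8(1096L))),
                   1L)  # overlap 4 of 8
  expect_identical(nrow(mirna_mask_candidates(list(rec), site8(1095L))),
                   0L)  # overlap 3 of 8
  # odd length 7: ceil(7/2) = 4 needed
  site7 <- bed("chr1", 1097L, 1104L)
  expect_identical(nrow(mirna_mask_candidates(list(rec), site7)), 1L)
  expect_no_error(mirna_mask_candidates(list(rec), bed("chr1", 5L, 6L)[0, ]))
  expect_error(
    mirna_mask_candidates(list(rec),
                          data.frame(chrom = "chr1", start = 5L, end = 5L,
                                     name = ".", score = 0,
                                     strand = "+")),
    "zero-length")
})

test_that("site-set intersection equals merge on identical inputs", {
  set.seed(15)
  x <- bed("chr1", st <- sample(0:200, 12), st + sample(5:25, 12, TRUE))
  expect_identical(intersect_site_sets(x, x), merge_regions(x))
  a <- bed("chr1", 0L, 10L)
  b <- bed("chr1", 5L, 20L)
  ab <- intersect_site_sets(a, b)
  expect_identical(c(ab$start, ab$end), c(5L, 10L))
  expect_identical(nrow(intersect_site_sets(a, bed("chr1", 50L, 60L))),
                   0L)
})

test_that("SMD requires Alu inside both the region and the 3'UTR of a
           coding target", {
  # region [1850,1950) genomic = tx [850,950); UTR3 = tx [800,1000)
  rec <- mk_interaction(850L, 950L)
  inside <- bed("chr1", 1860L, 1900L)
  expect_identical(nrow(smd_candidates(list(rec), inside)), 1L)
  # same geometry, noncoding target: dropped
  rec_nc <- mk_interaction(850L, 950L, biotype = "noncoding")
  expect_identical(nrow(smd_candidates(list(rec_nc), inside)), 0L)
  # Alu crossing the CDS boundary: dropped
  rec2 <- mk_interaction(700L, 950L)  # region [1700,1950)
  straddle <- bed("chr1", 1780L, 1850L)
  expect_identical(nrow(smd_candidates(list(rec2), straddle)), 0L)
})

test_that("editing sites use half-open membership", {
  rec <- mk_interaction(100L, 200L)  # genomic [1100, 1200)
  expect_identical(nrow(editing_candidates(list(rec),
                                           bed("chr1", 1150L, 1151L))), 1L)
  expect_identical(nrow(editing_candidates(list(rec),
                                           bed("chr1", 1200L, 1201L))), 0L)
  expect_identical(nrow(editing_candidates(list(rec),
                                           bed("chr1", 1L, 2L)[0, ])), 0L)
  expect_error(editing_candidates(list(rec), bed("chr1", 10L, 12L)),
               "single-base")
})

test_that("filters are monotone in evidence and in interactions", {
  rec1 <- mk_interaction(100L, 200L)
  rec2 <- mk_interaction(300L, 400L)
  e1 <- bed("chr1", 1150L, 1151L)
  e2 <- bed("chr1", 1350L, 1351L)
  n_small <- nrow(editing_candidates(list(rec1), e1))
  n_more_sites <- nrow(editing_candidates(list(rec1), rbind(e1, e2)))
  n_more_ints <- nrow(editing_candidates(list(rec1, rec2),
                                         rbind(e1, e2)))
  expect_gte(n_more_sites, n_small)
  expect_gte(n_more_ints, n_more_sites)
  expect_identical(n_more_ints, 2L)
})

test_that("filters commute with partitioning the interaction set", {
  rec1 <- mk_interaction(100L, 200L)
  rec2 <- mk_interaction(300L, 400L)
  sites <- rbind(bed("chr1", 1150L, 1151L), bed("chr1", 1350L, 1351L))
  together <- editing_candidates(list(rec1, rec2), sites)
  apart <- rbind(editing_candidates(list(rec1), sites),
                 editing_candidates(list(rec2), sites))
  expect_equal(together[order(together$evidence_start), ],
               apart[order(apart$evidence_start), ],
               ignore_attr = TRUE)
})
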