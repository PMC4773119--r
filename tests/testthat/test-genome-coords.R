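test_that("projection splits transcript intervals across exons", {
  mod <- toy_model()  # exons [100,200) [300,400) on +
  b <- project_to_genome(mod, 50, 150)
  expect_identical(b$start, c(150L, 300L))
  expect_identical(b$end, c(200L, 350L))
  # minus strand single exon
  mod2 <- toy_model(strand = "-",
                    exons = data.frame(start = 100L, end = 200L))
  b2 <- project_to_genome(mod2, 0, 10)
  expect_identical(c(b2$start, b2$end), c(190L, 200L))
  # pre-mRNA mode: no splitting
  mod3 <- toy_model(exons = data.frame(start = c(1000L, 1300L),
                                       end = c(1100L, 1400L)))
  b3 <- project_to_genome(mod3, 10, 20, mode = "pre-mRNA")
  expect_identical(c(b3$start, b3$end), c(1010L, 1020L))
  expect_error(project_to_genome(mod, 150, 250), "exceeds")
})

test_that("transcript->genome->transcript is the identity", {
  set.seed(11)
  for (i in 1:60) {
    mod <- random_model()
    L <- tx_length(mod)
    s <- sample(0:(L - 2L), 1)
    e <- sample((s + 1L):L, 1)
    blocks <- project_to_genome(mod, s, e)
    expect_identical(sum(blocks$end - blocks$start), e - s)
    expect_identical(project_to_transcript(mod, blocks), c(s, e))
  }
})

test_that("merge_regions covers the union minimally and is idempotent", {
  b <- bed("chr1", c(0L, 5L), c(10L, 15L))
  mb <- merge_regions(b)
  expect_identical(c(mb$start, mb$end), c(0L, 15L))
  d <- bed("chr1", c(0L, 10L), c(5L, 15L))
  expect_identical(nrow(merge_regions(d)), 2L)
  # strand-aware: opposite strands never merge
  s <- bed("chr1", c(0L, 5L), c(10L, 15L), strand = c("+", "-"))
  expect_identical(nrow(merge_regions(s)), 2L)
  set.seed(12)
  for (i in 1:20) {
    x <- bed("chr1", st <- sample(0:100, 10), st + sample(1:30, 10))
    m1 <- merge_regions(x)
    expect_identical(merge_regions(m1), m1)
    expect_true(all(m1$start[-1] > m1$end[-nrow(m1)]))
  }
})

test_that("length is conserved when merging disjoint intervals", {
  set.seed(13)
  st <- seq(0L, 180L, by = 20L)
  x <- bed("chr1", st, st + sample(1:10, length(st), replace = TRUE))
  expect_identical(sum(x$end - x$start),
                   sum(merge_regions(x)$end - merge_regions(x)$start))
})

test_that("region classification follows CDS/UTR containment rules", {
  mod <- toy_model(exons = data.frame(start = 0L, end = 500L),
                   cds = c(120L, 380L))
  mk <- function(s, e, mode = "mRNA") duplex_alignment(
    "l", "t", 0L, e - s, s, e, 50L, strrep("G", e - s),
    strrep("C", e - s), 1000L,
    if (mode == "mRNA") tx_length(mod) else premrna_length(mod), mode)
  expect_identical(classify_region(mk(400, 450), mod), "UTR3")
  expect_identical(classify_region(mk(0, 100), mod), "UTR5")
  expect_identical(classify_region(mk(150, 300), mod), "CDS")
  expect_identical(classify_region(mk(100, 150), mod), "CDS_UTR")
  expect_identical(classify_region(mk(360, 400), mod), "CDS_UTR")
  nc <- toy_model(exons = data.frame(start = 0L, end = 500L),
                  biotype = "noncoding")
  expect_identical(classify_region(mk(150, 300), nc), "noncoding")
  no_cds <- toy_model(exons = data.frame(start = 0L, end = 500L))
  expect_error(classify_region(mk(0, 10), no_cds), "lacks a CDS")
})

test_that("every interaction gets exactly one region class", {
  set.seed(14)
  mod <- toy_model(exons = data.frame(start = 0L, end = 500L),
                   cds = c(120L, 380L))
  classes <- c("CDS", "UTR5", "UTR3", "CDS_UTR", "noncoding")
  for (i in 1:50) {
    s <- sample(0:498, 1)
    e <- sample((s + 1L):500L, 1)
    a <- duplex_alignment("l", "t", 0L, e - s, s, e, 50L,
                          strrep("G", e - s), strrep("C", e - s),
                          1000L, 500L, "mRNA")
    cl <- classify_region(a, mod)
    expect_length(cl, 1)
    expect_true(cl %in% classes)
  }
})

test_that("cis requires overlap on opposite strands of one chromosome", {
  a <- bed("chr1", 100L, 500L, strand = "+")
  b <- bed("chr1", 300L, 700L, strand = "-")
  expect_identical(classify_cis_trans(a, b), "cis")
  b2 <- bed("chr1", 300L, 700L, strand = "+")
  expect_identical(classify_cis_trans(a, b2), "trans")
  b3 <- bed("chr2", 300L, 700L, strand = "-")
  expect_identical(classify_cis_trans(a, b3), "trans")
  b4 <- bed("chr1", 500L, 700L, strand = "-")  # abutting, no overlap
  expect_identical(classify_cis_trans(a, b4), "trans")
})
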