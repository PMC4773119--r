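# shared helpers: random sequences, planted duplexes, toy models

rnd_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# plant the antiparallel complement of target[ws, ws+len) into lnc at lpos
plant_pair <- function(lnc_len, target_len, len, lpos, ws, gc = 0.6) {
  target <- rnd_seq(target_len)
  lnc <- rnd_seq(lnc_len)
  w <- rnd_seq(len, gc = gc)
  substr(target, ws + 1L, ws + len) <- w
  substr(lnc, lpos + 1L, lpos + len) <- revcomp(w)
  list(lnc = lnc, target = target, window = w)
}

# two-exon plus-strand toy model
toy_model <- function(chrom = "chr1", strand = "+",
                      exons = data.frame(start = c(100L, 300L),
                                         end = c(200L, 400L)),
                      cds = NULL, biotype = "protein_coding",
                      id = "t1", gene = "g1") {
  transcript_model(id, gene, chrom, strand, exons, cds, biotype)
}

# random multi-exon model for property tests
random_model <- function(n_exons = sample(1:4, 1),
                         strand = sample(c("+", "-"), 1)) {
  starts <- cumsum(sample(50:300, n_exons * 2)) + 100L
  exons <- data.frame(start = starts[seq(1, 2 * n_exons, 2)],
                      end = starts[seq(2, 2 * n_exons, 2)])
  transcript_model("t", "g", "chr1", strand, exons, NULL, "noncoding")
}

expect_same_alignments <- function(a, b) {
  expect_identical(alignments_df(a), alignments_df(b))
}
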