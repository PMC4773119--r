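#' Fixture configuration
#'
#' Study-condition defaults for the synthetic fixture: a two-chromosome
#' miniature genome carrying 20 three-exon genes (600/700-nt introns, so
#' one intron per transcript exceeds the 2 x 250-nt retention window and
#' gets an interior mask), 10 lncRNA loci, six planted duplexes of known
#' composition (25 G:C + 15 A:T pairs, score 130 by the closed form
#' 4*GC + 2*AT) plus one natural-antisense duplex arising from a lncRNA
#' overlapping its target gene on the opposite strand, hand-placed
#' regulatory features with known rule outcomes, and a three-library
#' read-mapping design with known co-expression truth.
#'
#' @param n_genes_per_chrom genes per chromosome (layout is fixed-pitch).
#' @param lnc_len lncRNA locus length (nt).
#' @param flank intron retention width used by the pre-mRNA mode.
#' @param plant_len,plant_gc planted-duplex length and G:C pair count.
#' @param barrier anti-pairing columns written on each side of a plant so
#'   that local extension beyond the planted window is impossible in
#'   practice.
#' @return configuration list.
#' @export
fixture_config <- function(n_genes_per_chrom = 10L, lnc_len = 800L,
                           flank = 250L, plant_len = 40L, plant_gc = 25L,
                           barrier = 10L) {
  list(n_genes_per_chrom = n_genes_per_chrom,
       chrom_len = 400L + n_genes_per_chrom * 3200L + 400L,
       lnc_len = lnc_len, flank = flank,
       plant_len = plant_len, plant_gc = plant_gc, barrier = barrier,
       exon_offsets = data.frame(start = c(0L, 750L, 1650L),
                                 end = c(150L, 950L, 1800L)),
       utr5_len = 120L, cds_tx_end = 380L,
       noncoding_genes = c(4L, 8L, 14L, 18L),
       libraries = c("lib1", "lib2", "lib3"))
}

# ---- simulator-local coordinate arithmetic (closed forms, kept separate
# ---- from the package's projection code so the truth table is independent)

.sim_exons_tx_order <- function(m) {
  ex <- m$exons
  if (m$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

# mature tx position -> genomic position
.sim_tx2g <- function(m, p) {
  ex <- .sim_exons_tx_order(m)
  w <- ex$end - ex$start
  cs <- cumsum(c(0L, w))
  k <- findInterval(p, cs, rightmost.closed = FALSE)
  off <- p - cs[k]
  if (m$strand == "+") ex$start[k] + off else ex$end[k] - 1L - off
}

# pre-mRNA position -> genomic position
.sim_pre2g <- function(m, p) {
  span <- c(m$exons$start[1], m$exons$end[nrow(m$exons)])
  if (m$strand == "+") span[1] + p else span[2] - 1L - p
}

# mature tx position -> pre-mRNA position
.sim_tx2pre <- function(m, p) {
  span <- c(m$exons$start[1], m$exons$end[nrow(m$exons)])
  g <- .sim_tx2g(m, p)
  if (m$strand == "+") g - span[1] else span[2] - 1L - g
}

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# read / write a transcript-strand base through the genome character pool
.sim_read_base <- function(pool, m, gpos) {
  b <- pool[[m$chrom]][gpos + 1L]
  if (m$strand == "-") unname(.comp[b]) else b
}

.sim_write_base <- function(pool, m, gpos, base) {
  pool[[m$chrom]][gpos + 1L] <-
    if (m$strand == "-") unname(.comp[base]) else base
  pool
}

# a base that cannot positively pair with `b` in a duplex
.nonpairing <- c(A = "C", C = "C", G = "G", T = "T", N = "A")

.sim_extract_tx <- function(pool, m) {
  s <- paste(unlist(lapply(seq_len(nrow(m$exons)), function(k)
    pool[[m$chrom]][(m$exons$start[k] + 1L):m$exons$end[k]])),
    collapse = "")
  if (m$strand == "-") .revcomp(s) else s
}

#' Generate the synthetic fixture
#'
#' Builds the miniature genome, transcript models, lncRNA and target
#' sequences with planted duplexes, regulatory feature sets and
#' read-mapping records described in [fixture_config()], together with a
#' machine-readable truth table: every planted duplex with its expected
#' transcript-space and pre-mRNA-space coordinates and closed-form score,
#' the expected count surviving each regulatory filter, and the expected
#' co-expression/balance flags. Fully deterministic given `seed`.
#'
#' @param config from [fixture_config()].
#' @param seed integer seed.
#' @return a fixture bundle: `genome`, `models`, `lnc`, `targets`,
#'   `features` (list of BEDs), `mappings`, `truth`, `config`, `seed`.
#' @export
make_fixture <- function(config = fixture_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  npc <- cfg$n_genes_per_chrom
  n_genes <- 2L * npc
  if (cfg$plant_len > cfg$lnc_len)
    stop("planted duplex longer than host sequence")

  pool <- list(
    chr1 = sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
    chr2 = sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE))

  # --- gene and lncRNA models on a fixed-pitch layout
  gene_start <- function(k) 400L + (k - 1L) * 3200L + 1200L  # k local
  models <- list()
  for (i in seq_len(n_genes)) {
    chrom <- if (i <= npc) "chr1" else "chr2"
    k <- if (i <= npc) i else i - npc
    G <- gene_start(k)
    strand <- if (i %% 2L == 1L) "+" else "-"
    coding <- !(i %in% cfg$noncoding_genes)
    exons <- data.frame(start = G + cfg$exon_offsets$start,
                        end = G + cfg$exon_offsets$end)
    m <- list(transcript_id = paste0("t_g", i), gene_id = paste0("g", i),
              chrom = chrom, strand = strand, exons = exons,
              biotype = if (coding) "protein_coding" else "noncoding",
              cds = NULL)
    if (coding) {
      g1 <- .sim_tx2g(m, cfg$utr5_len)
      g2 <- .sim_tx2g(m, cfg$cds_tx_end - 1L)
      m$cds <- c(min(g1, g2), max(g1, g2) + 1L)
    }
    models[[m$transcript_id]] <- m
  }
  # second isoform of gene 7 skipping the middle exon
  g7 <- models[["t_g7"]]
  models[["t_g7b"]] <- list(
    transcript_id = "t_g7b", gene_id = "g7", chrom = g7$chrom,
    strand = g7$strand, exons = g7$exons[c(1L, 3L), , drop = FALSE],
    biotype = "protein_coding", cds = g7$cds)

  lnc_models <- list()
  for (j in seq_len(10L)) {
    chrom <- if (j <= 5L) "chr1" else "chr2"
    k <- if (j <= 5L) j else j - 5L
    if (j == 1L) {
      # natural antisense: overlaps gene 1 (plus strand) by 50 bases
      G1 <- gene_start(1L)
      span <- c(G1 - 750L, G1 + 50L)
      strand <- "-"
    } else {
      s <- 400L + (k - 1L) * 3200L
      span <- c(s, s + cfg$lnc_len)
      strand <- "+"
    }
    lnc_models[[paste0("lnc", j)]] <- list(
      transcript_id = paste0("lnc", j), gene_id = paste0("lg", j),
      chrom = chrom, strand = strand,
      exons = data.frame(start = span[1], end = span[2]),
      biotype = "noncoding", cds = NULL)
  }

  # --- plant duplexes: window written into the target (through the
  #     genome), reverse complement into the lncRNA, anti-pairing barrier
  #     columns on both lncRNA flanks
  plant_window <- function() {
    sample(c(sample(c("G", "C"), cfg$plant_gc, replace = TRUE),
             sample(c("A", "T"), cfg$plant_len - cfg$plant_gc,
                    replace = TRUE)))
  }
  plant_score <- 4L * cfg$plant_gc + 2L * (cfg$plant_len - cfg$plant_gc)
  lnc_ps <- 300L

  plants <- list(
    list(name = "p1", lnc = "lnc1", tx = "t_g1", space = "tx", ws = 400L),
    list(name = "p2", lnc = "lnc2", tx = "t_g2", space = "tx", ws = 200L),
    list(name = "p3", lnc = "lnc3", tx = "t_g3", space = "tx", ws = 360L),
    list(name = "p4", lnc = "lnc4", tx = "t_g4", space = "tx", ws = 200L),
    list(name = "p5", lnc = "lnc5", tx = "t_g5", space = "pre", ws = 130L),
    list(name = "p6", lnc = "lnc6", tx = "t_g6", space = "pre", ws = 200L))

  windows <- list()
  for (p in plants) {
    W <- plant_window()
    windows[[p$name]] <- W
    tm <- models[[p$tx]]
    map <- if (p$space == "tx") .sim_tx2g else .sim_pre2g
    for (o in seq_len(cfg$plant_len))
      pool <- .sim_write_base(pool, tm, map(tm, p$ws + o - 1L), W[o])
    lm <- lnc_models[[p$lnc]]
    S <- strsplit(.revcomp(paste(W, collapse = "")), "")[[1]]
    for (o in seq_len(cfg$plant_len))
      pool <- .sim_write_base(pool, lm, .sim_tx2g(lm, lnc_ps + o - 1L),
                              S[o])
  }
  # barriers after all windows are in place
  tlen_of <- function(tm, space) {
    if (space == "tx") sum(tm$exons$end - tm$exons$start)
    else tm$exons$end[nrow(tm$exons)] - tm$exons$start[1]
  }
  for (p in plants) {
    tm <- models[[p$tx]]
    lm <- lnc_models[[p$lnc]]
    map <- if (p$space == "tx") .sim_tx2g else .sim_pre2g
    tlen <- tlen_of(tm, p$space)
    we <- p$ws + cfg$plant_len
    for (f in seq_len(cfg$barrier)) {
      tp_left <- we - 1L + f          # partner of lnc position ps - f
      if (tp_left < tlen && lnc_ps - f >= 0L) {
        tb <- .sim_read_base(pool, tm, map(tm, tp_left))
        pool <- .sim_write_base(pool, lm, .sim_tx2g(lm, lnc_ps - f),
                                unname(.nonpairing[tb]))
      }
      tp_right <- p$ws - f            # partner of lnc position ps+len-1+f
      lp <- lnc_ps + cfg$plant_len - 1L + f
      if (tp_right >= 0L && lp < cfg$lnc_len) {
        tb <- .sim_read_base(pool, tm, map(tm, tp_right))
        pool <- .sim_write_base(pool, lm, .sim_tx2g(lm, lp),
                                unname(.nonpairing[tb]))
      }
    }
  }

  # --- natural antisense duplex p0: lnc1's first 50 bases are the exact
  #     antiparallel complement of gene 1's first 50 exonic bases
  G1 <- gene_start(1L)
  ov <- pool$chr1[(G1 + 1L):(G1 + 50L)]
  p0_gc <- sum(ov %in% c("G", "C"))
  p0_score <- 4L * p0_gc + 2L * (50L - p0_gc)

  # --- truth: duplex table
  tm_of <- function(p) models[[p$tx]]
  duplexes <- data.frame(
    name = "p0", lnc_id = "lnc1", target_id = "t_g1",
    lnc_start = 0L, lnc_end = 50L, tx_start = 0L, tx_end = 50L,
    pre_start = 0L, pre_end = 50L, score = p0_score,
    in_mrna = TRUE, in_premrna = TRUE, junction = FALSE,
    region_class = "UTR5", locality = "cis", stringsAsFactors = FALSE)
  region_of <- list(p1 = "UTR3", p2 = "CDS", p3 = "CDS_UTR",
                    p4 = "noncoding", p5 = NA_character_,
                    p6 = NA_character_)
  for (p in plants) {
    tm <- tm_of(p)
    we <- p$ws + cfg$plant_len
    if (p$space == "tx") {
      tx_s <- p$ws; tx_e <- we
      pre_s <- min(.sim_tx2pre(tm, p$ws), .sim_tx2pre(tm, we - 1L))
      pre_e <- pre_s + cfg$plant_len
    } else {
      tx_s <- NA_integer_; tx_e <- NA_integer_
      pre_s <- p$ws; pre_e <- we
    }
    junction <- p$name == "p5"
    duplexes <- rbind(duplexes, data.frame(
      name = p$name, lnc_id = p$lnc, target_id = p$tx,
      lnc_start = lnc_ps, lnc_end = lnc_ps + cfg$plant_len,
      tx_start = tx_s, tx_end = tx_e, pre_start = pre_s, pre_end = pre_e,
      score = plant_score,
      in_mrna = p$space == "tx", in_premrna = TRUE, junction = junction,
      region_class = region_of[[p$name]],
      locality = if (p$lnc == "lnc1") "cis" else "trans",
      stringsAsFactors = FALSE))
  }

  # --- regulatory features placed against the planted genomic regions
  reg_g <- function(name) {
    d <- duplexes[duplexes$name == name, ]
    tm <- models[[d$target_id]]
    space <- if (is.na(d$tx_start)) "pre" else "tx"
    map <- if (space == "pre") .sim_pre2g else .sim_tx2g
    a <- map(tm, if (space == "pre") d$pre_start else d$tx_start)
    b <- map(tm, (if (space == "pre") d$pre_end else d$tx_end) - 1L)
    c(min(a, b), max(a, b) + 1L)  # genomic half-open
  }
  st_of <- function(name)
    models[[duplexes$target_id[duplexes$name == name]]]$strand
  ch_of <- function(name)
    models[[duplexes$target_id[duplexes$name == name]]]$chrom
  r1 <- reg_g("p1"); r2 <- reg_g("p2"); r3 <- reg_g("p3")
  r4 <- reg_g("p4"); r5 <- reg_g("p5")
  features <- list(
    clip = bed(chrom = rep(ch_of("p5"), 3L),
               start = c(r5[1] + 8L, r5[1] - 10L, r5[1] + 10L),
               end = c(r5[1] + 28L, r5[1] + 10L, r5[1] + 25L),
               name = c("C1_contained", "C2_partial", "C3_strand"),
               strand = c(st_of("p5"), st_of("p5"),
                          if (st_of("p5") == "+") "-" else "+")),
    mirna = bed(chrom = rep(ch_of("p2"), 2L),
                start = c(r2[1] + 10L, r2[1] - 5L),
                end = c(r2[1] + 18L, r2[1] + 3L),
                name = c("M1_half_in", "M2_below_half"),
                strand = st_of("p2")),
    alu = bed(chrom = c(ch_of("p1"), ch_of("p3"), ch_of("p4")),
              start = c(r1[1] + 5L, r3[1] + 10L, r4[1] + 10L),
              end = c(r1[1] + 29L, r3[1] + 30L, r4[1] + 34L),
              name = c("U1_utr3", "U2_cds_straddle", "U3_noncoding"),
              strand = c(st_of("p1"), st_of("p3"), st_of("p4"))),
    editing = bed(chrom = c(ch_of("p3"), ch_of("p1")),
                  start = c(r3[1] + 10L, r1[2]),
                  end = c(r3[1] + 11L, r1[2] + 1L),
                  name = c("E1_inside", "E2_exclusive_end"),
                  strand = c(st_of("p3"), st_of("p1"))))

  # --- expression design
  counts <- list(
    lib1 = c(lnc1 = 50L, t_g1 = 1L, lnc2 = 4L, t_g2 = 8L, lnc3 = 1L,
             t_g3 = 48L, lnc5 = 2L, t_g5 = 2L, lnc6 = 2L, t_g6 = 2L),
    lib2 = c(lnc4 = 3L),
    lib3 = c(t_g4 = 3L))
  rows <- list()
  for (lib in names(counts)) {
    for (tx in names(counts[[lib]])) {
      n <- counts[[lib]][tx]
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("%s_%s_%d", lib, tx, seq_len(n)),
        library_id = lib, transcript_id = tx, mismatches = 0L,
        stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    read_id = "r_multi11", library_id = "lib1",
    transcript_id = rep("t_g9", 11L), mismatches = 0L,
    stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    read_id = "r_iso", library_id = "lib1",
    transcript_id = c("t_g7", "t_g7b"), mismatches = 0L,
    stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    read_id = "r_twogene", library_id = "lib1",
    transcript_id = c("t_g8", "t_g9"), mismatches = 0L,
    stringsAsFactors = FALSE)
  mappings <- do.call(rbind, rows)

  truth <- list(
    duplexes = duplexes,
    regulatory = c(splice_mask = 1L, mirna_mask = 1L, smd = 1L,
                   editing = 1L),
    splice_site_class = "constitutive",
    coexpression = data.frame(
      name = c("p0", "p1", "p2", "p3", "p4", "p5", "p6"),
      lnc_id = c("lnc1", "lnc1", "lnc2", "lnc3", "lnc4", "lnc5", "lnc6"),
      target_id = c("t_g1", "t_g1", "t_g2", "t_g3", "t_g4", "t_g5",
                    "t_g6"),
      coexpressed = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
      balanced = c(TRUE, TRUE, TRUE, FALSE, NA, TRUE, TRUE),
      stringsAsFactors = FALSE))

  genome <- vapply(pool, paste, character(1), collapse = "")
  all_models <- c(models, lnc_models)
  tm_objects <- lapply(all_models, function(m)
    transcript_model(m$transcript_id, m$gene_id, m$chrom, m$strand,
                     m$exons, m$cds, m$biotype))
  targets <- vapply(models, function(m) .sim_extract_tx(pool, m),
                    character(1))
  names(targets) <- names(models)
  lnc <- vapply(lnc_models, function(m) .sim_extract_tx(pool, m),
                character(1))
  names(lnc) <- names(lnc_models)

  list(genome = genome, models = tm_objects[names(models)],
       lnc_models = tm_objects[names(lnc_models)],
       lnc = lnc, targets = targets, features = features,
       mappings = mappings, truth = truth, config = cfg, seed = seed)
}

#' Write a fixture bundle to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `lnc.fa`, `targets.fa`,
#' `clip.bed`, `mirna.bed`, `alu.bed`, `editing.bed`, `mappings.tsv` and
#' `truth.json`; byte-identical for identical `(config, seed)`.
#'
#' @param fixture from [make_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(fixture$genome, p("genome.fa"))
  write_fasta(fixture$targets, p("targets.fa"))
  write_fasta(fixture$lnc, p("lnc.fa"))
  write_gtf(c(fixture$models, fixture$lnc_models), p("annotation.gtf"))
  write_bed(fixture$features$clip, p("clip.bed"))
  write_bed(fixture$features$mirna, p("mirna.bed"))
  write_bed(fixture$features$alu, p("alu.bed"))
  write_bed(fixture$features$editing, p("editing.bed"))
  write.table(fixture$mappings, p("mappings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fixture$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' Perturb a single fixture feature
#'
#' Moves one hand-placed regulatory feature to its rule-violating variant;
#' exactly one rule-engine count should drop by exactly one.
#'
#' @param fixture from [make_fixture()].
#' @param which `"alu"` (outside the 3'UTR), `"mirna"` (overlap below
#'   half), `"clip"` (partially outside the interaction region) or
#'   `"editing"` (moved to the region's exclusive end).
#' @return modified fixture.
#' @export
perturb_fixture <- function(fixture,
                            which = c("alu", "mirna", "clip", "editing")) {
  which <- match.arg(which)
  f <- fixture$features
  d <- fixture$truth$duplexes
  reg_end <- function(name) {
    # recompute the genomic end of a planted region from the truth table
    row <- d[d$name == name, ]
    tm <- fixture$models[[row$target_id]]
    if (is.na(row$tx_start)) {
      g <- sort(premrna_to_genomic(tm, c(row$pre_start, row$pre_end - 1L)))
    } else {
      pr <- project_to_genome(tm, row$tx_start, row$tx_end)
      g <- c(min(pr$start), max(pr$end) - 1L)
    }
    c(g[1], g[2] + 1L)
  }
  if (which == "alu") {
    f$alu[1, c("start", "end")] <- f$alu[1, c("start", "end")] - 60L
  } else if (which == "mirna") {
    r2 <- reg_end("p2")
    f$mirna[1, c("start", "end")] <- c(r2[2] - 3L, r2[2] + 5L)
  } else if (which == "clip") {
    r5 <- reg_end("p5")
    f$clip[1, c("start", "end")] <- c(r5[1] - 10L, r5[1] + 10L)
  } else {
    r3 <- reg_end("p3")
    f$editing[1, c("start", "end")] <- c(r3[2], r3[2] + 1L)
  }
  fixture$features <- f
  fixture$truth$regulatory[[c(alu = "smd", mirna = "mirna_mask",
                              clip = "splice_mask",
                              editing = "editing")[which]]] <-
    fixture$truth$regulatory[[c(alu = "smd", mirna = "mirna_mask",
                                clip = "splice_mask",
                                editing = "editing")[which]]] - 1L
  fixture
}

#' Check pipeline outputs against a fixture truth table
#'
#' Stage-by-stage exact comparison: alignment coordinates and scores per
#' mode, the junction-spanning subset, the per-mechanism regulatory counts
#' and the co-expression flags.
#'
#' @param results a [run_pipeline()] bundle (or a list with elements
#'   `mrna_alignments`, `premrna_alignments`, `junction_alignments`,
#'   `regulatory`, `coexpression`; stages absent from `results` with no
#'   corresponding truth are skipped, but a truth entry without its stage
#'   is an error).
#' @param truth a fixture `truth` list.
#' @return list with `pass` (logical) and a `stages` data.frame.
#' @export
truth_check <- function(results, truth) {
  stages <- data.frame(stage = character(), pass = logical(),
                       detail = character(), stringsAsFactors = FALSE)
  add <- function(stage, pass, detail = "") {
    stages <<- rbind(stages, data.frame(stage = stage, pass = pass,
                                        detail = detail,
                                        stringsAsFactors = FALSE))
  }
  cmp_alns <- function(alns, expected, coord) {
    got <- alignments_df(alns)
    got <- got[order(got$lnc_id, got$target_id, got$target_start), ]
    exp_df <- data.frame(lnc_id = expected$lnc_id,
                         target_id = expected$target_id,
                         lnc_start = expected$lnc_start,
                         lnc_end = expected$lnc_end,
                         target_start = expected[[paste0(coord, "_start")]],
                         target_end = expected[[paste0(coord, "_end")]],
                         score = expected$score, stringsAsFactors = FALSE)
    exp_df <- exp_df[order(exp_df$lnc_id, exp_df$target_id,
                           exp_df$target_start), ]
    rownames(got) <- rownames(exp_df) <- NULL
    identical(got[, names(exp_df)], exp_df)
  }
  d <- truth$duplexes
  if (is.null(results$mrna_alignments))
    stop("missing stage output: mrna_alignments")
  add("mrna_alignments",
      cmp_alns(results$mrna_alignments, d[d$in_mrna, ], "tx"))
  if (!is.null(results$premrna_alignments)) {
    add("premrna_alignments",
        cmp_alns(results$premrna_alignments, d[d$in_premrna, ], "pre"))
    if (is.null(results$junction_alignments))
      stop("missing stage output: junction_alignments")
    add("junction_alignments",
        cmp_alns(results$junction_alignments, d[d$junction, ], "pre"))
  }
  if (is.null(results$regulatory))
    stop("missing stage output: regulatory")
  got_reg <- vapply(names(truth$regulatory), function(mech)
    sum(results$regulatory$mechanism == mech), 0L)
  add("regulatory",
      all(got_reg == unlist(truth$regulatory)),
      paste(names(got_reg), got_reg, collapse = " "))
  if (is.null(results$coexpression))
    stop("missing stage output: coexpression")
  co <- truth$coexpression
  ok <- TRUE
  for (i in seq_len(nrow(co))) {
    row <- results$coexpression[
      results$coexpression$lnc_id == co$lnc_id[i] &
        results$coexpression$target_id == co$target_id[i], , drop = FALSE]
    if (nrow(row) == 0L) next  # pair not in this mode's interaction set
    ok <- ok && all(row$coexpressed == co$coexpressed[i])
  }
  add("coexpression", ok)
  list(pass = all(stages$pass), stages = stages)
}
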