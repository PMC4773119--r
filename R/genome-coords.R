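#' Project a transcript interval to genomic blocks
#'
#' Maps a 0-based half-open interval on a transcript's own 5'->3' axis to
#' genomic intervals. In `"mRNA"` mode the interval is split across exons;
#' in `"pre-mRNA"` mode the transcript axis is the unspliced span so the
#' projection is a single block. Minus-strand transcripts map 5'->3' onto
#' descending genomic coordinates.
#'
#' @param model a [transcript_model].
#' @param start,end 0-based half-open interval on the transcript
#'   (mature for `"mRNA"`, unspliced for `"pre-mRNA"`).
#' @param mode `"mRNA"` or `"pre-mRNA"`.
#' @return BED `data.frame` of genomic blocks in genomic order, strand =
#'   transcript strand.
#' @export
#' @examples
#' m <- transcript_model("t", "g", "chr1", "+",
#'                       data.frame(start = c(100, 300), end = c(200, 400)))
#' project_to_genome(m, 50, 150)  # [150,200) and [300,350)
project_to_genome <- function(model, start, end, mode = "mRNA") {
  stopifnot(inherits(model, "transcript_model"), start >= 0, start < end)
  if (mode == "pre-mRNA") {
    if (end > premrna_length(model))
      stop("interval exceeds pre-mRNA length")
    g <- sort(premrna_to_genomic(model, c(start, end - 1L)))
    return(bed(model$chrom, g[1], g[2] + 1L, strand = model$strand))
  }
  if (end > tx_length(model)) stop("interval exceeds transcript length")
  ex_g <- .exons_tx_order(model)    # genomic exons, transcript order
  ex_t <- .exons_tx(model)          # same exons on the transcript axis
  blocks <- NULL
  for (k in seq_len(nrow(ex_t))) {
    s <- max(start, ex_t$start[k])
    e <- min(end, ex_t$end[k])
    if (s >= e) next
    off_s <- s - ex_t$start[k]
    off_e <- e - ex_t$start[k]
    if (model$strand == "+") {
      gs <- ex_g$start[k] + off_s
      ge <- ex_g$start[k] + off_e
    } else {
      gs <- ex_g$end[k] - off_e
      ge <- ex_g$end[k] - off_s
    }
    blocks <- rbind(blocks, data.frame(start = gs, end = ge))
  }
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  bed(model$chrom, blocks$start, blocks$end, strand = model$strand)
}

#' Map genomic blocks back to a transcript interval
#'
#' Inverse of [project_to_genome()]: each block must lie within the
#' transcript's exons (mature mode) or span (pre-mRNA mode); the union of
#' the mapped pieces must be one contiguous transcript interval, which is
#' returned.
#'
#' @param model a [transcript_model].
#' @param blocks BED `data.frame` of genomic blocks.
#' @param mode `"mRNA"` or `"pre-mRNA"`.
#' @return integer `(start, end)`, 0-based half-open on the transcript.
#' @export
project_to_transcript <- function(model, blocks, mode = "mRNA") {
  stopifnot(inherits(model, "transcript_model"), nrow(blocks) >= 1L)
  if (mode == "pre-mRNA") {
    pos <- genomic_to_premrna(model, c(min(blocks$start),
                                       max(blocks$end) - 1L))
    return(c(min(pos), max(pos) + 1L))
  }
  ex_g <- .exons_tx_order(model)
  ex_t <- .exons_tx(model)
  pieces <- NULL
  for (i in seq_len(nrow(blocks))) {
    hit <- which(ex_g$start <= blocks$start[i] & ex_g$end >= blocks$end[i])
    if (length(hit) != 1L)
      stop("genomic block [", blocks$start[i], ",", blocks$end[i],
           ") not contained in a single exon")
    if (model$strand == "+") {
      ts <- ex_t$start[hit] + (blocks$start[i] - ex_g$start[hit])
      te <- ex_t$start[hit] + (blocks$end[i] - ex_g$start[hit])
    } else {
      ts <- ex_t$start[hit] + (ex_g$end[hit] - blocks$end[i])
      te <- ex_t$start[hit] + (ex_g$end[hit] - blocks$start[i])
    }
    pieces <- rbind(pieces, data.frame(start = ts, end = te))
  }
  pieces <- pieces[order(pieces$start), , drop = FALSE]
  if (nrow(pieces) > 1L &&
      any(pieces$start[-1] != pieces$end[-nrow(pieces)]))
    stop("genomic blocks do not map to one contiguous transcript interval")
  c(pieces$start[1], pieces$end[nrow(pieces)])
}

#' Merge genomic intervals to unique positions
#'
#' Minimal sorted set of non-overlapping intervals covering the union,
#' computed per (chromosome, strand) group; adjacent half-open intervals
#' are merged. Idempotent. Interval algebra is delegated to
#' [GenomicRanges::reduce].
#'
#' @param x BED `data.frame`.
#' @return merged BED `data.frame`.
#' @export
merge_regions <- function(x) {
  if (nrow(x) == 0L) return(.empty_bed())
  gr <- GenomicRanges::reduce(.bed_to_gr(x))
  out <- .gr_to_bed(GenomicRanges::sort(gr))
  out[order(out$chrom, out$strand, out$start), , drop = FALSE]
}

#' Strand-aware intersection of two interval sets
#'
#' Each set is merged first; the result is the per-strand common part.
#'
#' @param a,b BED `data.frame`s.
#' @return BED `data.frame` of the intersection.
#' @export
intersect_regions <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(.empty_bed())
  gr <- GenomicRanges::intersect(.bed_to_gr(a), .bed_to_gr(b))
  out <- .gr_to_bed(GenomicRanges::sort(gr))
  out[order(out$chrom, out$strand, out$start), , drop = FALSE]
}

# CDS span in mature-transcript coordinates
.cds_tx <- function(model) {
  if (is.null(model$cds)) return(NULL)
  blocks <- NULL
  for (k in seq_len(nrow(model$exons))) {
    s <- max(model$exons$start[k], model$cds[1])
    e <- min(model$exons$end[k], model$cds[2])
    if (s < e) blocks <- rbind(blocks, data.frame(start = s, end = e))
  }
  tx <- project_to_transcript(
    model, bed(model$chrom, blocks$start, blocks$end,
               strand = model$strand))
  tx
}

# CDS span on the pre-mRNA axis
.cds_premrna <- function(model) {
  if (is.null(model$cds)) return(NULL)
  pos <- genomic_to_premrna(model, c(model$cds[1], model$cds[2] - 1L))
  c(min(pos), max(pos) + 1L)
}

#' Classify the mRNA region of a target interval
#'
#' Non-coding targets always classify as `"noncoding"`. For protein-coding
#' targets, an interval entirely within the 5'UTR, CDS or 3'UTR takes that
#' class; an interval overlapping the CDS and at least one UTR is
#' `"CDS_UTR"`. In pre-mRNA mode the same rule is applied on the unspliced
#' axis (the CDS span then includes its introns); an interval touching both
#' UTRs but no CDS takes the UTR with the larger overlap (ties go to the
#' 3'UTR).
#'
#' @param alignment a [duplex_alignment] whose target is `model`.
#' @param model the target's [transcript_model].
#' @return one of `"CDS"`, `"UTR5"`, `"UTR3"`, `"CDS_UTR"`, `"noncoding"`.
#' @export
classify_region <- function(alignment, model) {
  stopifnot(inherits(alignment, "duplex_alignment"),
            inherits(model, "transcript_model"))
  if (model$biotype == "noncoding") return("noncoding")
  if (is.null(model$cds))
    stop("protein-coding transcript ", model$transcript_id, " lacks a CDS")
  if (alignment$mode == "pre-mRNA") {
    cds <- .cds_premrna(model)
    L <- premrna_length(model)
  } else {
    cds <- .cds_tx(model)
    L <- tx_length(model)
  }
  s <- alignment$target_start
  e <- alignment$target_end
  ov <- function(a, b) max(0L, min(e, b) - max(s, a))
  o5 <- ov(0L, cds[1])
  oc <- ov(cds[1], cds[2])
  o3 <- ov(cds[2], L)
  if (oc > 0L && (o5 > 0L || o3 > 0L)) return("CDS_UTR")
  if (oc > 0L) return("CDS")
  if (o5 > 0L && o3 > 0L) return(if (o3 >= o5) "UTR3" else "UTR5")
  if (o5 > 0L) return("UTR5")
  "UTR3"
}

#' Classify an interaction as cis or trans
#'
#' `"cis"` iff the two gene spans lie on the same chromosome, their genomic
#' spans overlap by at least one base, and they are transcribed from
#' opposite strands; everything else — including same-strand overlap — is
#' `"trans"`.
#'
#' @param span_a,span_b single-row BED `data.frame`s (gene spans).
#' @return `"cis"` or `"trans"`.
#' @export
classify_cis_trans <- function(span_a, span_b) {
  stopifnot(nrow(span_a) == 1L, nrow(span_b) == 1L)
  same_chrom <- span_a$chrom == span_b$chrom
  overlap <- span_a$start < span_b$end && span_b$start < span_a$end
  opposite <- span_a$strand != span_b$strand
  if (same_chrom && overlap && opposite) "cis" else "trans"
}

#' Genomic span of a gene
#'
#' Union extent of all the gene's transcripts' exons.
#'
#' @param models list of `transcript_model`s (any genes).
#' @param gene_id the gene.
#' @return single-row BED `data.frame`.
#' @export
gene_span <- function(models, gene_id) {
  ms <- Filter(function(m) m$gene_id == gene_id, models)
  if (length(ms) == 0L) stop("no transcripts for gene ", gene_id)
  starts <- vapply(ms, function(m) tx_span(m)[1], 0L)
  ends <- vapply(ms, function(m) tx_span(m)[2], 0L)
  bed(ms[[1]]$chrom, min(starts), max(ends), name = gene_id,
      strand = ms[[1]]$strand)
}

#' Build genome-annotated interaction records
#'
#' Projects each alignment's lncRNA and target intervals to merged genomic
#' blocks, classifies the target region and the cis/trans locality, and
#' attaches everything as an `interaction_record`.
#'
#' @param alignments list of [duplex_alignment]s.
#' @param models named list of target `transcript_model`s.
#' @param lnc_models named list of lncRNA `transcript_model`s.
#' @return list of `interaction_record` objects.
#' @export
annotate_interactions <- function(alignments, models, lnc_models) {
  out <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    tm <- models[[a$target_id]]
    lm <- lnc_models[[a$lnc_id]]
    if (is.null(tm)) stop("no transcript model for target ", a$target_id)
    if (is.null(lm)) stop("no transcript model for lncRNA ", a$lnc_id)
    tg <- merge_regions(project_to_genome(tm, a$target_start, a$target_end,
                                          mode = a$mode))
    lg <- merge_regions(project_to_genome(lm, a$lnc_start, a$lnc_end,
                                          mode = "mRNA"))
    rec <- structure(list(
      id = sprintf("%s|%s|%d", a$lnc_id, a$target_id, i),
      alignment = a,
      lnc_genomic = lg,
      target_genomic = tg,
      target_model = tm,
      region_class = classify_region(a, tm),
      locality = classify_cis_trans(
        gene_span(lnc_models, lm$gene_id),
        gene_span(models, tm$gene_id))),
      class = "interaction_record")
    out[[i]] <- rec
  }
  out
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf("interaction %s: %s, %s, score %d\n", x$id, x$region_class,
              x$locality, x$alignment$score))
  invisible(x)
}

#' BED of interaction regions
#'
#' One row per genomic fragment of each interaction's target region, named
#' `lnc_id|target_id|region_class|locality`.
#'
#' @param interactions list of `interaction_record`s.
#' @return BED `data.frame`.
#' @export
interactions_bed <- function(interactions) {
  if (length(interactions) == 0L) return(.empty_bed())
  do.call(rbind, lapply(interactions, function(r) {
    b <- r$target_genomic
    b$name <- sprintf("%s|%s|%s|%s", r$alignment$lnc_id,
                      r$alignment$target_id, r$region_class, r$locality)
    b$score <- r$alignment$score
    b
  }))
}
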