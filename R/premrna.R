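#' Transcript model
#'
#' Exon structure, strand, optional CDS span and biotype of one transcript;
#' the anchor for all coordinate arithmetic. Exons and CDS are genomic,
#' 0-based half-open; exons must be sorted by genomic start and
#' non-overlapping.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer `start`, `end` (0-based half-open,
#'   genomic, ascending, non-overlapping).
#' @param cds optional genomic `(start, end)` of the coding span, or `NULL`.
#' @param biotype `"protein_coding"` or `"noncoding"`.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"),
            biotype %in% c("protein_coding", "noncoding"),
            is.data.frame(exons), nrow(exons) >= 1L,
            all(exons$start < exons$end))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons overlap in transcript ", transcript_id)
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (length(cds) != 2L || cds[1] >= cds[2])
      stop("cds must be a genomic (start, end) with start < end")
    if (cds[1] < exons$start[1] || cds[2] > exons$end[nrow(exons)])
      stop("cds outside exon span in transcript ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand,
                 exons = data.frame(start = as.integer(exons$start),
                                    end = as.integer(exons$end)),
                 cds = cds, biotype = biotype),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript %s (gene %s) %s:%s [%d exon(s), %s]\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$biotype))
  invisible(x)
}

#' Mature-transcript length (sum of exon widths)
#' @param model a `transcript_model`.
#' @export
tx_length <- function(model) sum(model$exons$end - model$exons$start)

#' Genomic span and pre-mRNA length
#' @param model a `transcript_model`.
#' @return integer `(start, end)` genomic span, 0-based half-open.
#' @export
tx_span <- function(model) c(model$exons$start[1],
                             model$exons$end[nrow(model$exons)])

#' @rdname tx_span
#' @export
premrna_length <- function(model) diff(tx_span(model))

# exon intervals in transcript (mature) coordinates, transcript order
.exons_tx <- function(model) {
  w <- model$exons$end - model$exons$start
  if (model$strand == "-") w <- rev(w)
  e <- cumsum(w)
  data.frame(start = c(0L, e[-length(e)]), end = e)
}

# exon-intron boundary positions on the pre-mRNA axis
.premrna_junctions <- function(model) {
  span <- tx_span(model)
  ex <- .exons_tx_order(model)
  pre_ex <- if (model$strand == "+") {
    data.frame(start = ex$start - span[1], end = ex$end - span[1])
  } else {
    data.frame(start = span[2] - ex$end, end = span[2] - ex$start)
  }
  if (nrow(pre_ex) < 2L) return(integer())
  sort(unique(c(pre_ex$end[-nrow(pre_ex)], pre_ex$start[-1L])))
}

# exons in genomic order matching transcript order
.exons_tx_order <- function(model) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

#' Read transcript models from GTF-like annotation
#'
#' Consumes a tab-delimited annotation with `exon` and `CDS` feature rows
#' (1-based inclusive coordinates on disk, converted to internal 0-based
#' half-open), `gene_id`/`transcript_id` attributes and an optional
#' `transcript_biotype`. Parsing is delegated to [rtracklayer::import].
#'
#' @param path GTF file.
#' @return named list of [transcript_model] objects.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  is_exon <- md$type == "exon"
  is_cds <- md$type == "CDS"
  tx_ids <- unique(md$transcript_id[is_exon])
  out <- list()
  for (tid in tx_ids) {
    rows <- gr[is_exon & md$transcript_id == tid]
    crows <- gr[is_cds & md$transcript_id == tid]
    bt <- S4Vectors::mcols(rows)$transcript_biotype
    bt <- if (is.null(bt) || all(is.na(bt))) "protein_coding" else bt[1]
    if (!bt %in% c("protein_coding", "noncoding"))
      bt <- if (grepl("coding", bt)) "protein_coding" else "noncoding"
    cds <- NULL
    if (length(crows) > 0L)
      cds <- c(min(GenomicRanges::start(crows)) - 1L,
               max(GenomicRanges::end(crows)))
    out[[tid]] <- transcript_model(
      transcript_id = tid,
      gene_id = S4Vectors::mcols(rows)$gene_id[1],
      chrom = as.character(GenomicRanges::seqnames(rows))[1],
      strand = as.character(GenomicRanges::strand(rows))[1],
      exons = data.frame(start = GenomicRanges::start(rows) - 1L,
                         end = GenomicRanges::end(rows)),
      cds = cds, biotype = bt)
  }
  out
}

#' Write transcript models as GTF
#'
#' @param models list of `transcript_model` objects.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  lines <- character()
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                     m$gene_id, m$transcript_id, m$biotype)
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, paste(m$chrom, "duplexscan", "exon",
                              m$exons$start[i] + 1L, m$exons$end[i], ".",
                              m$strand, ".", attrs, sep = "\t"))
    if (!is.null(m$cds)) {
      # emit CDS split by exon
      for (i in seq_len(nrow(m$exons))) {
        s <- max(m$exons$start[i], m$cds[1])
        e <- min(m$exons$end[i], m$cds[2])
        if (s < e)
          lines <- c(lines, paste(m$chrom, "duplexscan", "CDS", s + 1L, e,
                                  ".", m$strand, "0", attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build an intron-masked pre-mRNA query
#'
#' Returns the unspliced transcript sequence (5'->3' on the transcript
#' strand) in which, for every intron longer than `2 * flank`, positions
#' farther than `flank` bases from both splice sites are replaced with `N`.
#' The masked base count per intron is therefore
#' `max(0, intron_length - 2 * flank)`. Masking substitutes rather than
#' deletes, so pre-mRNA positions map to genomic positions by a single
#' strand-aware affine transform (see [premrna_to_genomic()]).
#'
#' @param model a [transcript_model].
#' @param genome named character vector or `DNAStringSet` of chromosomes.
#' @param flank retained intron width at each splice site (default 250 nt).
#' @return object of class `premrna_query`: `id`, `seq`, the `model`,
#'   `junctions` (pre-mRNA 0-based positions of exon-intron boundaries) and
#'   `masked` (data.frame of masked pre-mRNA intervals).
#' @export
build_premrna_query <- function(model, genome, flank = 250L) {
  stopifnot(inherits(model, "transcript_model"), flank >= 0)
  flank <- as.integer(flank)
  genome <- .as_seq_set(genome, "chr")
  if (!model$chrom %in% names(genome))
    stop("genome lacks chromosome ", model$chrom)
  span <- tx_span(model)
  chrom_seq <- genome[[model$chrom]]
  if (span[2] > nchar(chrom_seq))
    stop("exon outside chromosome bounds for ", model$transcript_id)
  s <- substr(chrom_seq, span[1] + 1L, span[2])
  if (model$strand == "-") s <- .revcomp(s)
  # exon intervals in pre-mRNA coordinates (transcript order)
  ex <- .exons_tx_order(model)
  pre_ex <- if (model$strand == "+") {
    data.frame(start = ex$start - span[1], end = ex$end - span[1])
  } else {
    data.frame(start = span[2] - ex$end, end = span[2] - ex$start)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  masked <- data.frame(start = integer(), end = integer())
  junctions <- integer()
  if (nrow(pre_ex) > 1L) {
    for (k in seq_len(nrow(pre_ex) - 1L)) {
      is_ <- pre_ex$end[k]
      ie <- pre_ex$start[k + 1L]
      junctions <- c(junctions, is_, ie)
      if (ie - is_ > 2L * flank) {
        ms <- is_ + flank
        me <- ie - flank
        chars[(ms + 1L):me] <- "N"
        masked <- rbind(masked, data.frame(start = ms, end = me))
      }
    }
  }
  structure(list(id = model$transcript_id, seq = paste(chars, collapse = ""),
                 model = model, junctions = sort(unique(junctions)),
                 masked = masked, flank = as.integer(flank)),
            class = "premrna_query")
}

#' Pre-mRNA <-> genomic coordinate maps
#'
#' The pre-mRNA axis is the transcript-strand 5'->3' walk over the genomic
#' span, so the map is affine and invertible for every position (masked or
#' not).
#'
#' @param x a `premrna_query` or `transcript_model`.
#' @param pos integer vector of 0-based positions.
#' @return integer vector of mapped 0-based positions.
#' @export
premrna_to_genomic <- function(x, pos) {
  model <- if (inherits(x, "premrna_query")) x$model else x
  span <- tx_span(model)
  stopifnot(all(pos >= 0L), all(pos < diff(span)))
  if (model$strand == "+") span[1] + pos else span[2] - 1L - pos
}

#' @rdname premrna_to_genomic
#' @export
genomic_to_premrna <- function(x, pos) {
  model <- if (inherits(x, "premrna_query")) x$model else x
  span <- tx_span(model)
  stopifnot(all(pos >= span[1]), all(pos < span[2]))
  if (model$strand == "+") pos - span[1] else span[2] - 1L - pos
}

#' Does a pre-mRNA alignment span an exon-intron junction?
#'
#' `TRUE` iff the alignment's target interval contains at least one
#' exon-intron boundary strictly in its interior — at least one paired or
#' gapped column on each side — which is the defining property of a
#' lncRNA-pre-mRNA interaction. An alignment ending exactly at a boundary
#' does not span it.
#'
#' @param alignment a [duplex_alignment] with `mode == "pre-mRNA"` whose
#'   target is the pre-mRNA query.
#' @param query the `premrna_query` (or a `transcript_model`) the alignment
#'   targets.
#' @return logical.
#' @export
spans_junction <- function(alignment, query) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  if (alignment$mode != "pre-mRNA")
    stop("spans_junction requires a pre-mRNA-mode alignment")
  junctions <- if (inherits(query, "premrna_query")) {
    query$junctions
  } else {
    .premrna_junctions(query)
  }
  any(junctions > alignment$target_start & junctions < alignment$target_end)
}
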