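#' Read a FASTA file of transcript sequences
#'
#' Sequences are upper-cased and U is normalised to T, so RNA and DNA
#' sources coexist in one internal DNA alphabet (A,C,G,T,N). Duplicate ids
#' and empty sequences are errors. gzip input is read transparently.
#'
#' @param path FASTA file (optionally gzipped).
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- .normalize_seq(as.character(x))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0L],
                                             collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (!is(x, "XStringSet")) x <- Biostrings::DNAStringSet(unlist(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED file of genomic features
#'
#' Accepts 3-6 columns. Intervals are kept in BED's native 0-based
#' half-open convention. A missing strand column defaults to `"+"` with a
#' warning; `start >= end` is an error reported with its line number.
#'
#' @param path BED file (optionally gzipped).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (class `c("bed", "data.frame")`).
#' @export
read_bed <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(.empty_bed())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 0L)
  if (any(ncol < 3L))
    stop("BED line ", lineno[which(ncol < 3L)[1]], ": fewer than 3 columns")
  get <- function(i, default) vapply(seq_along(fields), function(k) {
    if (ncol[k] >= i) fields[[k]][i] else default
  }, character(1))
  start <- suppressWarnings(as.integer(get(2, NA_character_)))
  end <- suppressWarnings(as.integer(get(3, NA_character_)))
  if (any(is.na(start) | is.na(end)))
    stop("BED line ", lineno[which(is.na(start) | is.na(end))[1]],
         ": non-integer coordinates")
  bad <- start >= end | start < 0L
  if (any(bad))
    stop("BED line ", lineno[which(bad)[1]], ": invalid interval [",
         start[which(bad)[1]], ", ", end[which(bad)[1]], ")")
  strand <- get(6, NA_character_)
  if (any(is.na(strand))) {
    warning("strand missing on ", sum(is.na(strand)),
            " BED line(s); defaulting to '+'")
    strand[is.na(strand)] <- "+"
  }
  if (!all(strand %in% c("+", "-")))
    stop("BED line ", lineno[which(!strand %in% c("+", "-"))[1]],
         ": strand must be + or -")
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  df <- data.frame(chrom = get(1, NA), start = start, end = end,
                   name = get(4, "."), score = score, strand = strand,
                   stringsAsFactors = FALSE)
  class(df) <- c("bed", "data.frame")
  df
}

.empty_bed <- function() {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character(), score = numeric(),
                   strand = character(), stringsAsFactors = FALSE)
  class(df) <- c("bed", "data.frame")
  df
}

#' Build a BED data.frame from vectors
#'
#' @param chrom,start,end,name,score,strand BED columns (0-based half-open).
#' @return a BED `data.frame`.
#' @export
bed <- function(chrom, start, end, name = ".", score = 0, strand = "+") {
  stopifnot(all(start < end), all(start >= 0),
            all(strand %in% c("+", "-")))
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), name = name, score = score,
                   strand = strand, stringsAsFactors = FALSE)
  class(df) <- c("bed", "data.frame")
  df
}

#' Write a BED data.frame to disk
#'
#' @param x BED `data.frame` (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  write.table(x[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# BED data.frame <-> GRanges (1-based closed) conversions used internally
# for interval algebra; all user-facing coordinates stay 0-based half-open.
.bed_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}

.gr_to_bed <- function(gr, name = ".", score = 0) {
  if (length(gr) == 0L) return(.empty_bed())
  bed(chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      name = name, score = score,
      strand = as.character(GenomicRanges::strand(gr)))
}

#' Write duplex alignments as MAF
#'
#' One `a`-line per alignment with the score and mode, then two `s`-lines:
#' the lncRNA row (strand `+`, 5'->3') and the target row (strand `-`,
#' displayed in pairing orientation, i.e. the target bases 3'->5' under the
#' lncRNA; the start field is the interval start on the target's own 5'->3'
#' axis, 0-based). This duplex dialect round-trips losslessly through
#' [read_maf()].
#'
#' @param alignments list of `duplex_alignment` objects.
#' @param path output path.
#' @export
write_maf <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 program=duplexscan", con)
  for (a in alignments) {
    if (!inherits(a, "duplex_alignment")) stop("not a duplex_alignment")
    writeLines(sprintf("a score=%d mode=%s", a$score, a$mode), con)
    writeLines(sprintf("s %s %d %d + %d %s", a$lnc_id, a$lnc_start,
                       a$lnc_end - a$lnc_start, a$lnc_len, a$lnc_row), con)
    writeLines(sprintf("s %s %d %d - %d %s", a$target_id, a$target_start,
                       a$target_end - a$target_start, a$target_len,
                       a$target_row), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read duplex alignments from MAF
#'
#' @param path MAF file written by [write_maf()].
#' @return list of `duplex_alignment` objects.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^a ", lines[i]))
      stop("malformed MAF block at: ", lines[i])
    score <- as.integer(sub(".*score=(-?[0-9]+).*", "\\1", lines[i]))
    mode <- sub(".*mode=([^ ]+).*", "\\1", lines[i])
    if (i + 2L > length(lines) || !grepl("^s ", lines[i + 1L]) ||
        !grepl("^s ", lines[i + 2L]))
      stop("malformed MAF block: expected two s-lines after ", lines[i])
    sl <- function(line) {
      f <- strsplit(sub("^s +", "", line), " +")[[1]]
      if (length(f) != 6L) stop("malformed MAF s-line: ", line)
      list(id = f[1], start = as.integer(f[2]), size = as.integer(f[3]),
           strand = f[4], srclen = as.integer(f[5]), row = f[6])
    }
    q <- sl(lines[i + 1L])
    t <- sl(lines[i + 2L])
    out[[length(out) + 1L]] <- duplex_alignment(
      lnc_id = q$id, target_id = t$id,
      lnc_start = q$start, lnc_end = q$start + q$size,
      target_start = t$start, target_end = t$start + t$size,
      score = score, lnc_row = q$row, target_row = t$row,
      lnc_len = q$srclen, target_len = t$srclen, mode = mode)
    i <- i + 3L
  }
  out
}
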