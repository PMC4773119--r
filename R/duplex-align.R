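#' @title Duplex alignments
#' @description A `duplex_alignment` records a scored antiparallel
#' base-pairing between a lncRNA and a target RNA: half-open 0-based
#' intervals on each molecule's own 5'->3' axis, the integer score, and the
#' alignment rows. The target row is stored in pairing orientation (target
#' 3'->5', left-to-right under the lncRNA row), so column `k` pairs
#' `lnc[lnc_start + k']` with `target[target_end - 1 - k']` for the k'-th
#' non-gap position of each row.
#' @param lnc_id,target_id sequence identifiers.
#' @param lnc_start,lnc_end,target_start,target_end 0-based half-open
#'   intervals on the respective molecules.
#' @param score integer alignment score.
#' @param lnc_row,target_row aligned rows with `-` gaps (target row in
#'   pairing orientation).
#' @param lnc_len,target_len full molecule lengths.
#' @param mode `"mRNA"` or `"pre-mRNA"`.
#' @return an object of class `duplex_alignment`.
#' @export
duplex_alignment <- function(lnc_id, target_id, lnc_start, lnc_end,
                             target_start, target_end, score,
                             lnc_row, target_row, lnc_len, target_len,
                             mode = "mRNA") {
  stopifnot(nchar(lnc_row) == nchar(target_row),
            lnc_start >= 0, lnc_start < lnc_end, lnc_end <= lnc_len,
            target_start >= 0, target_start < target_end,
            target_end <= target_len,
            mode %in% c("mRNA", "pre-mRNA"))
  structure(list(lnc_id = lnc_id, target_id = target_id,
                 lnc_start = as.integer(lnc_start),
                 lnc_end = as.integer(lnc_end),
                 target_start = as.integer(target_start),
                 target_end = as.integer(target_end),
                 score = as.integer(score),
                 lnc_row = lnc_row, target_row = target_row,
                 lnc_len = as.integer(lnc_len),
                 target_len = as.integer(target_len),
                 mode = mode),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("duplex %s[%d,%d) ~ %s[%d,%d)  score %d  (%s)\n",
              x$lnc_id, x$lnc_start, x$lnc_end,
              x$target_id, x$target_start, x$target_end, x$score, x$mode))
  cat(" lnc    5'-", x$lnc_row, "-3'\n", sep = "")
  cat(" target 3'-", x$target_row, "-5'\n", sep = "")
  invisible(x)
}

#' Alignment columns of a duplex
#'
#' @param aln a `duplex_alignment`.
#' @return 2-row character matrix (lnc row, target row in pairing
#'   orientation) with `-` for gaps.
#' @export
alignment_columns <- function(aln) {
  stopifnot(inherits(aln, "duplex_alignment"))
  rbind(strsplit(aln$lnc_row, "", fixed = TRUE)[[1]],
        strsplit(aln$target_row, "", fixed = TRUE)[[1]])
}

#' Tabulate a list of duplex alignments
#'
#' @param alignments list of `duplex_alignment` objects.
#' @return data.frame with one row per alignment.
#' @export
alignments_df <- function(alignments) {
  if (length(alignments) == 0L)
    return(data.frame(lnc_id = character(), target_id = character(),
                      lnc_start = integer(), lnc_end = integer(),
                      target_start = integer(), target_end = integer(),
                      score = integer(), mode = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(alignments, function(a)
    data.frame(lnc_id = a$lnc_id, target_id = a$target_id,
               lnc_start = a$lnc_start, lnc_end = a$lnc_end,
               target_start = a$target_start, target_end = a$target_end,
               score = a$score, mode = a$mode, stringsAsFactors = FALSE)))
}

# coerce input sequence to (id, string)
.as_seq1 <- function(x, default_id) {
  if (is(x, "XStringSet")) {
    id <- names(x)[1]
    x <- as.character(x[[1]])
  } else if (is(x, "XString")) {
    id <- NULL
    x <- as.character(x)
  } else {
    id <- names(x)
    x <- as.character(x)
  }
  if (is.null(id) || !nzchar(id)) id <- default_id
  x <- .normalize_seq(x)
  .check_seq(x, default_id)
  list(id = id[1], seq = x)
}

#' Exact local duplex alignment by full dynamic programming
#'
#' Enumerates all maximal-scoring, mutually non-overlapping local
#' antiparallel duplexes between a lncRNA `q` and a target `t` with score at
#' least `min_score`. Internally `q` is aligned against `reverse(t)` with
#' the pairing matrix as the substitution matrix and affine gap costs, so a
#' match column is a duplex base pair (G:C, A:U or G:U wobble) and the hit
#' is mapped back onto `t`'s 5'->3' axis. Alignments are extracted greedily
#' by descending score, masking the lncRNA and target positions already
#' assigned; equal-score ties keep the alignment with the smaller
#' `(lnc_start, target_start)`.
#'
#' This is the exhaustive reference search; [align_duplex_seeded()] is the
#' production path with identical output above threshold.
#'
#' @param q lncRNA sequence (named character scalar or `DNAStringSet` of 1).
#' @param t target sequence.
#' @param matrix a `pairing_matrix`.
#' @param min_score integer reporting threshold (>= 1).
#' @param mode `"mRNA"` or `"pre-mRNA"` label carried on the alignments.
#' @param q_id,t_id identifier overrides.
#' @return list of [duplex_alignment] objects, descending score.
#' @export
#' @examples
#' a <- align_duplex_exact(c(q = "GGGAAA"), c(t = "TTTCCC"),
#'                         default_pairing_matrix(), min_score = 10)
#' a[[1]]$score  # 18
align_duplex_exact <- function(q, t, matrix = default_pairing_matrix(),
                               min_score, mode = "mRNA",
                               q_id = "query", t_id = "target") {
  stopifnot(inherits(matrix, "pairing_matrix"))
  if (min_score < 1L) stop("min_score must be >= 1")
  qq <- .as_seq1(q, q_id)
  tt <- .as_seq1(t, t_id)
  r <- .rev_chars(tt$seq)
  hits <- .cpp_sw_all(qq$seq, r, matrix$scores, matrix$gap_open,
                      matrix$gap_extend, as.integer(min_score))
  t_len <- nchar(tt$seq)
  lapply(hits, function(h)
    duplex_alignment(qq$id, tt$id,
                     lnc_start = h$qs, lnc_end = h$qe,
                     target_start = t_len - h$re,
                     target_end = t_len - h$rs,
                     score = h$score,
                     lnc_row = h$qrow, target_row = h$rrow,
                     lnc_len = nchar(qq$seq), target_len = t_len,
                     mode = mode))
}

#' Seeded local duplex search
#'
#' Production search path: a linear diagonal scan first looks for a seed —
#' a gapless complementary run (wobble pairs allowed) whose pairing score
#' reaches `seed_score` — and only seed-bearing pairs are submitted to the
#' full dynamic-programming extension. With the default
#' `seed_score = min(-mismatch, -(gap_open + gap_extend)) + 1` (7 under the
#' default matrix) the trigger is provably complete: runs inside an
#' alignment are separated by columns costing at least the mismatch
#' penalty, so an alignment whose every run scores below `seed_score` cannot
#' score above `seed_score - 1` in total. The output is therefore exactly
#' [align_duplex_exact()]'s above-threshold set, deterministically.
#'
#' @inheritParams align_duplex_exact
#' @param seed_score minimum pairing score of a gapless complementary run
#'   that triggers extension; `NULL` uses the completeness bound derived
#'   from the matrix. Values above the bound trade completeness for speed.
#' @return list of [duplex_alignment] objects.
#' @export
align_duplex_seeded <- function(q, t, matrix = default_pairing_matrix(),
                                min_score, seed_score = NULL,
                                mode = "mRNA",
                                q_id = "query", t_id = "target") {
  stopifnot(inherits(matrix, "pairing_matrix"))
  if (min_score < 1L) stop("min_score must be >= 1")
  if (is.null(seed_score)) seed_score <- .complete_seed_score(matrix)
  if (seed_score < 2L) stop("seed_score must be >= 2 (seeding degenerates)")
  if (min_score < seed_score)
    warning("min_score below seed_score: seeded search may be incomplete")
  qq <- .as_seq1(q, q_id)
  tt <- .as_seq1(t, t_id)
  if (!.cpp_seed_scan(qq$seq, .rev_chars(tt$seq), matrix$scores,
                      as.integer(seed_score)))
    return(list())
  align_duplex_exact(qq$seq, tt$seq, matrix, min_score, mode,
                     q_id = qq$id, t_id = tt$id)
}

#' Search a lncRNA set against a target set
#'
#' Runs the seeded duplex search for every (lncRNA, target) pair and
#' returns the union, stably sorted by `(target_id, lnc_id, score
#' descending)`.
#'
#' @param lnc_set,target_set named character vectors or `DNAStringSet`s.
#' @param matrix a `pairing_matrix`.
#' @param min_score reporting threshold (107 is the calibrated
#'   mature-transcript default, 108 the pre-mRNA default).
#' @param mode `"mRNA"` or `"pre-mRNA"`.
#' @param seeded use the seeded path (`FALSE` forces exhaustive DP).
#' @return list of [duplex_alignment] objects.
#' @export
search_transcriptome <- function(lnc_set, target_set,
                                 matrix = default_pairing_matrix(),
                                 min_score = 107L, mode = "mRNA",
                                 seeded = TRUE) {
  lnc_set <- .as_seq_set(lnc_set, "lnc")
  target_set <- .as_seq_set(target_set, "target")
  if (length(lnc_set) == 0L) stop("empty lncRNA set")
  if (length(target_set) == 0L) stop("empty target set")
  clash <- intersect(names(lnc_set), names(target_set))
  if (length(clash))
    stop("id collision between lncRNA and target sets: ",
         paste(clash, collapse = ", "))
  out <- list()
  for (ti in names(target_set)) {
    for (li in names(lnc_set)) {
      f <- if (seeded) align_duplex_seeded else align_duplex_exact
      hits <- f(lnc_set[[li]], target_set[[ti]], matrix, min_score,
                mode = mode, q_id = li, t_id = ti)
      out <- c(out, hits)
    }
  }
  if (length(out)) {
    ord <- order(vapply(out, `[[`, "", "target_id"),
                 vapply(out, `[[`, "", "lnc_id"),
                 -vapply(out, `[[`, 0L, "score"))
    out <- out[ord]
  }
  out
}

# coerce a sequence collection to a named list of strings
.as_seq_set <- function(x, prefix) {
  if (is(x, "XStringSet")) {
    v <- as.character(x)
  } else {
    v <- as.character(x)
    names(v) <- names(x)
  }
  if (length(v) == 0L) return(list())
  if (is.null(names(v)) || any(!nzchar(names(v))))
    names(v) <- paste0(prefix, seq_along(v))
  if (anyDuplicated(names(v)))
    stop("duplicate sequence ids in ", prefix, " set")
  v <- vapply(v, .normalize_seq, character(1))
  as.list(v)
}
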