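#' Default duplex pairing matrix
#'
#' The scoring economics of the duplex search: Watson-Crick G:C pairs score
#' 4, A:T (A:U) pairs 2, and G:T (G:U) wobble pairs 1; every other base
#' combination, and any combination involving `N`, scores the mismatch
#' penalty. Gap runs of length \eqn{g} cost `gap_open + g * gap_extend`
#' (penalties are negative), so a length-1 gap costs \eqn{-28} under the
#' defaults.
#'
#' These proportions (4/2/1) are the ones in long use for RNA-RNA
#' interaction scoring, e.g. in miRNA target-search algorithms; `N` scoring
#' as an ordinary mismatch is sufficient to keep alignments from crossing
#' masked intron interiors because the mismatch penalty dominates any run of
#' masked positions.
#'
#' @param gc,at,gt pairing scores for G:C, A:T and G:T.
#' @param mismatch score of any non-pairing column (must be negative).
#' @param gap_open,gap_extend affine gap penalties (negative; a gap run of
#'   length g costs `gap_open + g * gap_extend`).
#' @return An object of class `pairing_matrix`: a list with the 5x5 integer
#'   score matrix (`$scores`, rows/cols A,C,G,T,N) and the gap penalties.
#' @export
#' @examples
#' m <- default_pairing_matrix()
#' pair_score(m, "G", "C")  # 4
#' pair_score(m, "T", "G")  # 1 (wobble)
default_pairing_matrix <- function(gc = 4L, at = 2L, gt = 1L,
                                   mismatch = -6L,
                                   gap_open = -20L, gap_extend = -8L) {
  if (mismatch >= 0) stop("mismatch must be negative")
  if (gap_open > gap_extend || gap_extend >= 0)
    stop("gap penalties must satisfy gap_open <= gap_extend < 0")
  b <- c("A", "C", "G", "T", "N")
  s <- matrix(as.integer(mismatch), 5, 5, dimnames = list(b, b))
  s["G", "C"] <- s["C", "G"] <- as.integer(gc)
  s["A", "T"] <- s["T", "A"] <- as.integer(at)
  s["G", "T"] <- s["T", "G"] <- as.integer(gt)
  structure(list(scores = s, mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "pairing_matrix")
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat("Duplex pairing matrix (gap_open ", x$gap_open,
      ", gap_extend ", x$gap_extend, ")\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' Pairing score of two bases
#'
#' Symmetric lookup into a [pairing_matrix][default_pairing_matrix]:
#' `pair_score(m, x, y) == pair_score(m, y, x)`. Vectorised over `a`/`b`.
#'
#' @param matrix a `pairing_matrix`.
#' @param a,b character vectors of single bases in A,C,G,T,N.
#' @return integer vector of scores.
#' @export
pair_score <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "pairing_matrix"))
  a <- toupper(a); b <- toupper(b)
  bad <- !(a %in% rownames(matrix$scores)) | !(b %in% rownames(matrix$scores))
  if (any(bad))
    stop("non-alphabet base(s): ",
         paste(unique(c(a[bad], b[bad])), collapse = ", "))
  matrix$scores[cbind(a, b)]
}

#' Recompute an alignment score from its columns
#'
#' Sums pairing/mismatch scores over base columns and charges each maximal
#' gap run of length \eqn{g} a cost of `gap_open + g * gap_extend`. Used to
#' verify that every reported alignment's score reproduces from its columns.
#'
#' @param matrix a `pairing_matrix`.
#' @param columns a `duplex_alignment`, or a 2-row character matrix
#'   (row 1 = lncRNA 5'->3', row 2 = target in pairing orientation) with
#'   `"-"` marking gaps.
#' @return integer score.
#' @export
#' @examples
#' m <- default_pairing_matrix()
#' cols <- rbind(rep("G", 27), rep("C", 27))
#' alignment_score(m, cols)  # 108
alignment_score <- function(matrix, columns) {
  stopifnot(inherits(matrix, "pairing_matrix"))
  if (inherits(columns, "duplex_alignment"))
    columns <- alignment_columns(columns)
  if (is.list(columns) && !is.matrix(columns))
    columns <- rbind(columns[[1]], columns[[2]])
  if (!is.matrix(columns) || nrow(columns) != 2L)
    stop("columns must be a 2-row character matrix")
  qg <- columns[1, ] == "-"
  tg <- columns[2, ] == "-"
  if (any(qg & tg)) stop("column with two gaps")
  base_cols <- !qg & !tg
  s <- 0L
  if (any(base_cols))
    s <- s + sum(pair_score(matrix, columns[1, base_cols],
                            columns[2, base_cols]))
  for (gaps in list(qg, tg)) {
    r <- rle(gaps)
    runs <- r$lengths[r$values]
    if (length(runs))
      s <- s + sum(matrix$gap_open + runs * matrix$gap_extend)
  }
  as.integer(s)
}

#' Serialize / read a pairing matrix
#'
#' Whitespace-delimited 5x5 table (A,C,G,T,N rows and columns) preceded by
#' two comment lines carrying the gap penalties.
#'
#' @param matrix a `pairing_matrix`.
#' @param path file path.
#' @export
write_pairing_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pairing_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# gap_open", matrix$gap_open),
               paste("# gap_extend", matrix$gap_extend),
               paste(c(" ", colnames(matrix$scores)), collapse = "\t")), con)
  for (b in rownames(matrix$scores))
    writeLines(paste(c(b, matrix$scores[b, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_pairing_matrix
#' @export
read_pairing_matrix <- function(path) {
  lines <- readLines(path)
  gs <- lines[grepl("^# gap_", lines)]
  go <- as.integer(sub("^# gap_open\\s+", "", gs[grepl("gap_open", gs)]))
  ge <- as.integer(sub("^# gap_extend\\s+", "", gs[grepl("gap_extend", gs)]))
  body <- lines[!grepl("^#", lines)]
  tab <- read.delim(text = paste(body, collapse = "\n"), row.names = 1,
                    check.names = FALSE)
  s <- as.matrix(tab)
  storage.mode(s) <- "integer"
  b <- c("A", "C", "G", "T", "N")
  if (!identical(rownames(s), b) || !identical(colnames(s), b))
    stop("matrix file must have A,C,G,T,N rows and columns")
  m <- default_pairing_matrix(gap_open = go, gap_extend = ge)
  m$scores <- s
  m$mismatch <- s["A", "C"]
  m
}

# smallest seed score guaranteeing search completeness: pairing runs inside
# an alignment are separated by columns costing at least
# min(-mismatch, -(gap_open + gap_extend)), so any alignment scoring above
# that bound contains a gapless complementary run scoring >= bound + 1.
.complete_seed_score <- function(matrix) {
  min(-matrix$mismatch, -(matrix$gap_open + matrix$gap_extend)) + 1L
}

#' Expected chance alignments under a Gumbel fit
#'
#' Karlin-Altschul-style expectation \eqn{E(s) = K m n e^{-\lambda s}} for
#' the number of chance local duplex alignments scoring at least `s` in a
#' search space of total query length `m` and database length `n`.
#'
#' @param fit a `gumbel_fit` (from [calibrate_threshold()]) or a list with
#'   `lambda` and `K`.
#' @param s integer score(s).
#' @param m,n search-space dimensions; default those stored in the fit.
#' @return expected number of chance alignments with score >= `s`.
#' @export
expected_alignments <- function(fit, s, m = fit$m, n = fit$n) {
  fit$K * as.numeric(m) * as.numeric(n) * exp(-fit$lambda * s)
}

#' Smallest integer threshold meeting a chance-alignment target
#'
#' Closed-form inversion of `expected_alignments`: the smallest integer `s`
#' with \eqn{K m n e^{-\lambda s} <} `target`.
#'
#' @inheritParams expected_alignments
#' @param target maximum tolerated expected number of chance alignments.
#' @param min_positive floor applied to the result (a threshold below the
#'   smallest positive pairing score is meaningless); default 1.
#' @return integer threshold.
#' @export
#' @examples
#' fit <- list(lambda = 1, K = 0.1)
#' threshold_from_fit(fit, target = 1, m = 1000, n = 1000)  # 12
threshold_from_fit <- function(fit, target = 1, m = fit$m, n = fit$n,
                               min_positive = 1L) {
  stopifnot(target > 0, m > 0, n > 0)
  s <- floor(log(fit$K * as.numeric(m) * as.numeric(n) / target) /
               fit$lambda) + 1
  max(as.integer(s), as.integer(min_positive))
}

# Gumbel (location mu_i, common scale 1/lambda) maximum likelihood where
# mu_i = log(K * space_i) / lambda; spaces are the per-pair m*n products.
.gumbel_mle <- function(x, spaces) {
  s0 <- sd(x) * sqrt(6) / pi
  if (!is.finite(s0) || s0 <= 0) stop("degenerate null: all scores equal")
  lam0 <- 1 / s0
  mu0 <- mean(x) - 0.5772156649 * s0
  logK0 <- lam0 * mu0 - mean(log(spaces))
  nll <- function(p) {
    lam <- exp(p[1]); logK <- p[2]
    mu <- (logK + log(spaces)) / lam
    z <- (x - mu) * lam
    -sum(log(lam) - z - exp(-z))
  }
  fit <- optim(c(log(lam0), logK0), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(lambda = exp(fit$par[1]), K = exp(fit$par[2]))
}

#' Calibrate a score threshold against a shuffled-sequence null
#'
#' Empirical analogue of extreme-value E-value calibration: draws pairs of
#' null sequences (mononucleotide-composition-preserving shuffles of
#' `null_seqs`, or i.i.d. uniform sequences when none are given), records
#' the maximal local duplex score of each pair, fits Gumbel statistics
#' \eqn{E(s) = K m n e^{-\lambda s}} by maximum likelihood on the per-pair
#' maxima, and returns the smallest integer score at which fewer than
#' `target` chance alignments are expected over an `m` x `n` search space.
#' Rounding is upward (conservative). Deterministic given `seed`.
#'
#' @param matrix a `pairing_matrix`.
#' @param m,n total query / database lengths of the search space the
#'   threshold is meant for.
#' @param target tolerated expected number of chance alignments (default 1).
#' @param null_seqs optional character vector / `DNAStringSet` of sequences
#'   whose shuffles form the null; `NULL` means i.i.d. uniform sequences of
#'   length `null_len`.
#' @param n_null_pairs number of null pairs to score.
#' @param null_len length of generated null sequences.
#' @param seed integer seed.
#' @return a list of class `gumbel_fit`: `threshold`, `lambda`, `K`, `m`,
#'   `n`, and the null score maxima (`scores`).
#' @export
calibrate_threshold <- function(matrix, m, n, target = 1,
                                null_seqs = NULL, n_null_pairs = 200L,
                                null_len = 500L, seed = 1L) {
  stopifnot(inherits(matrix, "pairing_matrix"), m > 0, n > 0, target > 0,
            n_null_pairs >= 20L)
  set.seed(seed)
  if (!is.null(null_seqs)) {
    null_seqs <- as.character(null_seqs)
    draw <- function() {
      s <- strsplit(null_seqs[sample.int(length(null_seqs), 1L)], "")[[1]]
      paste(sample(s), collapse = "")
    }
  } else {
    draw <- function()
      paste(sample(c("A", "C", "G", "T"), null_len, replace = TRUE),
            collapse = "")
  }
  scores <- integer(n_null_pairs)
  spaces <- numeric(n_null_pairs)
  for (p in seq_len(n_null_pairs)) {
    q <- draw(); t <- draw()
    scores[p] <- .cpp_sw_best(q, .rev_chars(t), matrix$scores,
                              matrix$gap_open, matrix$gap_extend)
    spaces[p] <- nchar(q) * nchar(t)
  }
  if (length(unique(scores)) == 1L)
    stop("degenerate null: all scores equal")
  fit <- .gumbel_mle(scores, spaces)
  fit$m <- as.numeric(m)
  fit$n <- as.numeric(n)
  fit$scores <- scores
  fit$threshold <- threshold_from_fit(fit, target = target, m = m, n = n)
  class(fit) <- "gumbel_fit"
  fit
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat("Gumbel chance-alignment fit: lambda =", signif(x$lambda, 4),
      " K =", signif(x$K, 4), "\n")
  cat("search space", format(x$m, big.mark = ","), "x",
      format(x$n, big.mark = ","), "-> threshold", x$threshold, "\n")
  invisible(x)
}
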