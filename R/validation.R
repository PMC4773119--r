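#' Random-pair specificity test
#'
#' Draws `n_pairs` one-to-one (lncRNA, target) pairings without replacement
#' from two sequence pools, runs the seeded duplex search on each pair, and
#' reports the fraction with at least one alignment at or above
#' `threshold`. Under the premise that random pairings are non-interacting,
#' `specificity = 1 - hit_fraction`. Deterministic given `seed`.
#'
#' @param pool_lnc,pool_targets named character vectors or `DNAStringSet`s.
#' @param n_pairs number of random pairs (each pool must be at least this
#'   large).
#' @param matrix a `pairing_matrix`.
#' @param threshold reporting threshold.
#' @param seed integer seed.
#' @return list with `hit_fraction`, `specificity`, and a `hits`
#'   `data.frame` (one row per sampled pair, with the hit flag and best
#'   score).
#' @export
specificity_test <- function(pool_lnc, pool_targets, n_pairs,
                             matrix = default_pairing_matrix(),
                             threshold = 107L, seed = 1L) {
  pool_lnc <- .as_seq_set(pool_lnc, "lnc")
  pool_targets <- .as_seq_set(pool_targets, "target")
  if (length(pool_lnc) < n_pairs || length(pool_targets) < n_pairs)
    stop("pool smaller than n_pairs")
  set.seed(seed)
  li <- sample(names(pool_lnc), n_pairs)
  ti <- sample(names(pool_targets), n_pairs)
  hit <- logical(n_pairs)
  best <- integer(n_pairs)
  for (k in seq_len(n_pairs)) {
    alns <- align_duplex_seeded(pool_lnc[[li[k]]], pool_targets[[ti[k]]],
                                matrix, min_score = threshold,
                                q_id = li[k], t_id = ti[k])
    hit[k] <- length(alns) > 0L
    best[k] <- if (hit[k]) max(vapply(alns, `[[`, 0L, "score")) else 0L
  }
  list(hit_fraction = mean(hit), specificity = 1 - mean(hit),
       hits = data.frame(lnc_id = li, target_id = ti, hit = hit,
                         best_score = best, stringsAsFactors = FALSE))
}

#' Positive-set sensitivity test
#'
#' Fraction of curated/constructed positive (lncRNA, target) pairs with at
#' least one alignment at or above `threshold`.
#'
#' @param positive_pairs list of length-2 character vectors (or lists)
#'   `(lnc_seq, target_seq)`.
#' @param matrix a `pairing_matrix`.
#' @param threshold reporting threshold.
#' @return recovered fraction in `[0, 1]`.
#' @export
sensitivity_test <- function(positive_pairs,
                             matrix = default_pairing_matrix(),
                             threshold = 107L) {
  if (length(positive_pairs) == 0L) stop("empty positive set")
  rec <- vapply(positive_pairs, function(p) {
    length(align_duplex_seeded(p[[1]], p[[2]], matrix,
                               min_score = threshold)) > 0L
  }, logical(1))
  mean(rec)
}

#' Synthetic positive pairs with planted complements
#'
#' Builds `n` random sequence pairs, each carrying a planted perfect
#' antiparallel complement of `plant_len` bases with `plant_gc` G:C pairs
#' (the rest A:T), so every pair has a duplex of known score
#' `4 * plant_gc + 2 * (plant_len - plant_gc)`.
#'
#' @param n number of pairs.
#' @param len flanked sequence length of each molecule.
#' @param plant_len planted complement length.
#' @param plant_gc number of G:C pairs in the plant.
#' @param seed integer seed.
#' @return list of `(lnc, target)` character pairs, with the planted score
#'   in `attr(, "plant_score")`.
#' @export
make_positive_pairs <- function(n = 10L, len = 500L, plant_len = 30L,
                                plant_gc = 27L, seed = 1L) {
  stopifnot(plant_gc <= plant_len, plant_len < len)
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    target <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
    plant <- sample(c(sample(c("G", "C"), plant_gc, replace = TRUE),
                      sample(c("A", "T"), plant_len - plant_gc,
                             replace = TRUE)))
    pos <- sample.int(len - plant_len, 1L)
    substr(target, pos + 1L, pos + plant_len) <-
      paste(plant, collapse = "")
    lnc <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    lpos <- sample.int(len - plant_len, 1L)
    substr(lnc, lpos + 1L, lpos + plant_len) <-
      .revcomp(paste(plant, collapse = ""))
    out[[k]] <- c(lnc = lnc, target = target)
  }
  attr(out, "plant_score") <- 4L * plant_gc + 2L * (plant_len - plant_gc)
  out
}
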