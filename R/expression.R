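#' Read a mapping-summary table
#'
#' Tab-delimited records of read-to-transcript hits produced upstream by a
#' short-read mapper (one row per mapping position): columns `read_id`,
#' `library_id`, `transcript_id` and optionally `mismatches`. The mapper is
#' expected to have allowed at most one mismatch; rows violating that are
#' dropped with a warning rather than an error.
#'
#' @param path TSV file with a header.
#' @return `data.frame` of mapping records.
#' @export
read_mappings <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "library_id", "transcript_id")
  if (!all(need %in% names(df)))
    stop("mapping table must have columns: ", paste(need, collapse = ", "))
  if (!"mismatches" %in% names(df)) df$mismatches <- 0L
  df
}

#' Unique-read counting at transcript or gene level
#'
#' Reproduces the stringent unique-mapping filter: reads mapping to more
#' than ten positions are discarded; reads mapping to more than one gene
#' are removed; at `"transcript"` level a read must additionally hit
#' exactly one transcript, while at `"gene"` level any number of
#' transcripts of a single gene is allowed. Mapping rows with more than
#' one mismatch are dropped with a warning (the upstream mapper should
#' already have enforced this).
#'
#' @param mappings `data.frame` from [read_mappings()].
#' @param level `"transcript"` or `"gene"`.
#' @param gene_map named character vector mapping transcript_id to gene_id;
#'   every mapped transcript must be present.
#' @return `data.frame` with `unit_id`, `library_id`, `count`.
#' @export
filter_unique <- function(mappings, level = c("transcript", "gene"),
                          gene_map) {
  level <- match.arg(level)
  bad <- mappings$mismatches > 1L
  if (any(bad)) {
    warning(sum(bad), " mapping record(s) with >1 mismatch dropped")
    mappings <- mappings[!bad, , drop = FALSE]
  }
  missing <- setdiff(unique(mappings$transcript_id), names(gene_map))
  if (length(missing))
    stop("transcript(s) missing from gene_map: ",
         paste(missing, collapse = ", "))
  key <- paste(mappings$read_id, mappings$library_id, sep = "\r")
  groups <- split(seq_len(nrow(mappings)), key)
  rows <- lapply(groups, function(ix) {
    if (length(ix) > 10L) return(NULL)  # > 10 mapping positions
    tx <- mappings$transcript_id[ix]
    genes <- unique(gene_map[tx])
    if (length(genes) > 1L) return(NULL)  # multi-gene read
    if (level == "transcript") {
      if (length(unique(tx)) != 1L) return(NULL)
      data.frame(unit_id = tx[1], library_id = mappings$library_id[ix[1]],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(unit_id = unname(genes),
                 library_id = mappings$library_id[ix[1]],
                 stringsAsFactors = FALSE)
    }
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(unit_id = character(), library_id = character(),
                      count = integer(), stringsAsFactors = FALSE))
  agg <- aggregate(list(count = rep(1L, nrow(rows))),
                   by = list(unit_id = rows$unit_id,
                             library_id = rows$library_id), FUN = sum)
  agg[order(agg$unit_id, agg$library_id), , drop = FALSE]
}

#' Reads per kilobase per million uniquely mapped reads
#'
#' `unique_count / (length_nt / 1000) / (library_total / 1e6)`.
#'
#' @param unique_count uniquely mapped reads for the unit.
#' @param length_nt unit length in nucleotides (> 0).
#' @param library_total uniquely mapped reads in the library (> 0).
#' @return RPKM value.
#' @export
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
rpkm <- function(unique_count, length_nt, library_total) {
  if (any(length_nt <= 0)) stop("length_nt must be positive")
  if (any(library_total <= 0)) stop("library_total must be positive")
  unique_count / (length_nt / 1000) / (library_total / 1e6)
}

#' Per-transcript, per-library RPKM table
#'
#' Library totals are the unique-surviving read counts of that library at
#' the chosen level.
#'
#' @param counts `data.frame` from [filter_unique()].
#' @param lengths named numeric vector of unit lengths (nt).
#' @param libraries optional library universe (defaults to those observed).
#' @return object of class `expression_table`: `$rpkm` (units x libraries
#'   matrix), `$counts`, `$library_totals`.
#' @export
expression_table <- function(counts, lengths, libraries = NULL) {
  if (is.null(libraries)) libraries <- sort(unique(counts$library_id))
  units <- names(lengths)
  missing <- setdiff(unique(counts$unit_id), units)
  if (length(missing))
    stop("no length for unit(s): ", paste(missing, collapse = ", "))
  totals <- setNames(numeric(length(libraries)), libraries)
  obs <- tapply(counts$count, counts$library_id, sum)
  totals[names(obs)] <- obs
  m <- matrix(0, nrow = length(units), ncol = length(libraries),
              dimnames = list(units, libraries))
  for (i in seq_len(nrow(counts))) {
    lib <- counts$library_id[i]
    if (totals[lib] > 0)
      m[counts$unit_id[i], lib] <-
        rpkm(counts$count[i], lengths[counts$unit_id[i]], totals[lib])
  }
  structure(list(rpkm = m, counts = counts, library_totals = totals),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$rpkm), "units x", ncol(x$rpkm),
      "libraries\n")
  invisible(x)
}

.rpkm_of <- function(table, id) {
  if (!id %in% rownames(table$rpkm)) stop("unknown id: ", id)
  setNames(as.vector(table$rpkm[id, , drop = FALSE]),
           colnames(table$rpkm))
}

#' Are both interaction partners co-expressed?
#'
#' `TRUE` iff some library expresses both the lncRNA and the target above
#' `min_rpkm` (default 0, i.e. at least one uniquely mapped read each in
#' the same library).
#'
#' @param lnc_id,target_id transcript ids (must be in the table universe).
#' @param table an [expression_table].
#' @param min_rpkm expression cutoff (exclusive).
#' @return logical.
#' @export
coexpressed <- function(lnc_id, target_id, table, min_rpkm = 0) {
  l <- .rpkm_of(table, lnc_id)
  t <- .rpkm_of(table, target_id)
  any(l > min_rpkm & t > min_rpkm)
}

#' Expression-balance criterion
#'
#' In a library where both partners are expressed, the interaction is
#' plausibly stoichiometric when (i) the two expression values differ by
#' less than 10-fold, or (ii) the lncRNA is expressed in excess of the
#' target.
#'
#' @inheritParams coexpressed
#' @param library the library to evaluate in; both partners must be
#'   expressed there.
#' @return logical.
#' @export
expression_balanced <- function(lnc_id, target_id, table, library) {
  l <- .rpkm_of(table, lnc_id)[library]
  t <- .rpkm_of(table, target_id)[library]
  if (is.na(l) || is.na(t)) stop("unknown library: ", library)
  if (l <= 0 || t <= 0)
    stop("both partners must be expressed in library ", library)
  (l / t > 1) || (max(l, t) / min(l, t) < 10)
}

#' Co-expression report for interactions
#'
#' @param interactions list of `interaction_record`s (or
#'   `duplex_alignment`s).
#' @param table an [expression_table].
#' @param min_rpkm expression cutoff.
#' @return `data.frame` with one row per interaction: ids, `coexpressed`,
#'   and `balanced` (NA when never co-expressed; otherwise the balance
#'   criterion evaluated in the first co-expressing library).
#' @export
coexpression_report <- function(interactions, table, min_rpkm = 0) {
  rows <- lapply(interactions, function(r) {
    a <- if (inherits(r, "interaction_record")) r$alignment else r
    ids_known <- all(c(a$lnc_id, a$target_id) %in% rownames(table$rpkm))
    if (!ids_known)
      return(data.frame(lnc_id = a$lnc_id, target_id = a$target_id,
                        coexpressed = FALSE, balanced = NA,
                        stringsAsFactors = FALSE))
    co <- coexpressed(a$lnc_id, a$target_id, table, min_rpkm)
    bal <- NA
    if (co) {
      l <- .rpkm_of(table, a$lnc_id)
      t <- .rpkm_of(table, a$target_id)
      lib <- names(which(l > min_rpkm & t > min_rpkm))[1]
      bal <- expression_balanced(a$lnc_id, a$target_id, table, lib)
    }
    data.frame(lnc_id = a$lnc_id, target_id = a$target_id,
               coexpressed = co, balanced = bal, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
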