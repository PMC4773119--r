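#' Run the full interaction-discovery pipeline
#'
#' Orchestrates the end-to-end flow: read inputs, search lncRNAs against
#' targets (mature transcripts in `"mRNA"` mode; intron-masked unspliced
#' queries in `"pre-mRNA"` mode, followed by the junction-spanning filter),
#' project alignments to merged genomic regions, classify them, attach the
#' four regulatory-candidate annotations, and compute expression support.
#' Outputs are written to `out_dir`: `alignments.maf`, `interactions.bed`,
#' `regulatory.tsv`, `coexpression.tsv` and a `manifest.json` carrying the
#' tool version, a config hash and the seed; identical configs give
#' identical outputs.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `mode` ("mRNA" or "pre-mRNA"), `lnc_fasta`, `target_fasta`,
#'   `annotation`, `out_dir`, optionally `genome_fasta` (required for
#'   pre-mRNA mode), `clip_bed`, `mirna_bed`, `alu_bed`, `editing_bed`,
#'   `mappings_tsv`, `threshold` (default 107 for mRNA, 108 for pre-mRNA),
#'   `matrix_file`, `flank` (default 250), `seed` (default 1).
#' @return the result bundle, invisibly: alignments, interaction records,
#'   regulatory annotations, co-expression report, file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- match.arg(config$mode, c("mRNA", "pre-mRNA"))
  need <- c("lnc_fasta", "target_fasta", "annotation", "out_dir")
  for (k in need)
    if (is.null(config[[k]])) stop("config lacks required entry: ", k)
  for (k in c("lnc_fasta", "target_fasta", "annotation", "genome_fasta",
              "clip_bed", "mirna_bed", "alu_bed", "editing_bed",
              "mappings_tsv"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("missing input file: ", config[[k]])
  if (mode == "pre-mRNA" && is.null(config$genome_fasta))
    stop("pre-mRNA mode requires a genome_fasta")
  threshold <- config$threshold %||% (if (mode == "mRNA") 107L else 108L)
  flank <- config$flank %||% 250L
  seed <- config$seed %||% 1L
  matrix <- if (!is.null(config$matrix_file))
    read_pairing_matrix(config$matrix_file) else default_pairing_matrix()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  msg <- function(...) message("[duplexscan] ", ...)
  msg("mode ", mode, ", threshold ", threshold)

  lnc <- read_fasta(config$lnc_fasta)
  models <- read_transcript_models(config$annotation)
  lnc_models <- models[intersect(names(models), names(lnc))]
  target_models <- models[setdiff(names(models), names(lnc))]

  mrna_aln <- premrna_aln <- junction_aln <- NULL
  if (mode == "mRNA") {
    targets <- read_fasta(config$target_fasta)
    alns <- search_transcriptome(lnc, targets, matrix, threshold,
                                 mode = "mRNA")
    mrna_aln <- alns
    interactions <- annotate_interactions(alns, target_models, lnc_models)
  } else {
    genome <- read_fasta(config$genome_fasta)
    queries <- lapply(target_models, build_premrna_query, genome = genome,
                      flank = flank)
    qseqs <- setNames(vapply(queries, `[[`, "", "seq"), names(queries))
    alns <- search_transcriptome(lnc, qseqs, matrix, threshold,
                                 mode = "pre-mRNA")
    premrna_aln <- alns
    junction_aln <- Filter(function(a)
      spans_junction(a, queries[[a$target_id]]), alns)
    msg(length(junction_aln), " of ", length(alns),
        " alignments span an exon-intron junction")
    interactions <- annotate_interactions(junction_aln, target_models,
                                          lnc_models)
    alns <- junction_aln
  }
  msg(length(alns), " interaction(s) retained")

  features <- list(
    clip = if (!is.null(config$clip_bed)) read_bed(config$clip_bed)
           else .empty_bed(),
    mirna = if (!is.null(config$mirna_bed)) read_bed(config$mirna_bed)
            else .empty_bed(),
    alu = if (!is.null(config$alu_bed)) read_bed(config$alu_bed)
          else .empty_bed(),
    editing = if (!is.null(config$editing_bed))
      read_bed(config$editing_bed) else .empty_bed())
  regulatory <- regulatory_annotations(
    mrna_interactions = if (mode == "mRNA") interactions else list(),
    premrna_interactions = if (mode == "pre-mRNA") interactions
                           else list(),
    features = features, models = models)

  coexpr <- NULL
  if (!is.null(config$mappings_tsv)) {
    mappings <- read_mappings(config$mappings_tsv)
    gene_map <- vapply(models, `[[`, "", "gene_id")
    counts <- filter_unique(mappings, "transcript", gene_map)
    lengths <- vapply(models, tx_length, 0L)
    table <- expression_table(counts, lengths)
    coexpr <- coexpression_report(interactions, table)
  }

  # outputs
  p <- function(f) file.path(config$out_dir, f)
  write_maf(alns, p("alignments.maf"))
  write_bed(interactions_bed(interactions), p("interactions.bed"))
  write.table(regulatory, p("regulatory.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(coexpr))
    write.table(coexpr, p("coexpression.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  cfg_json <- jsonlite::toJSON(config[order(names(config))],
                               auto_unbox = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(tool = "duplexscan",
                   version = as.character(packageVersion("duplexscan")),
                   mode = mode, threshold = threshold, seed = seed,
                   config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)

  invisible(list(mode = mode,
                 mrna_alignments = mrna_aln,
                 premrna_alignments = premrna_aln,
                 junction_alignments = junction_aln,
                 interactions = interactions,
                 regulatory = regulatory,
                 coexpression = coexpr,
                 out_dir = config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
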