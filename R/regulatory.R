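#' @title Regulatory-candidate rule engine
#' @description Four independent, monotone filters attach mechanism-specific
#' evidence to genome-projected interactions: splice-signal masking
#' (protein-binding CLIP intervals entirely inside junction-spanning
#' pre-mRNA interaction regions, same strand), miRNA-site masking (at least
#' half of a merged CLIP-supported miRNA site inside an mRNA interaction),
#' Staufen-mediated-decay candidates (an Alu element entirely inside both
#' the interaction region and the target's 3'UTR, protein-coding targets
#' only) and A-to-I editing overlap (a single-base editing site inside the
#' interaction region). All rules are strand-aware and test containment
#' against the union of the interaction's genomic fragments.
#' @name regulatory
NULL

# evidence table constructor
.annotation_row <- function(rec, mechanism, ev, splice_site_class = NA) {
  data.frame(interaction_id = rec$id,
             lnc_id = rec$alignment$lnc_id,
             target_id = rec$alignment$target_id,
             mechanism = mechanism,
             evidence_chrom = ev$chrom, evidence_start = ev$start,
             evidence_end = ev$end, evidence_strand = ev$strand,
             splice_site_class = splice_site_class,
             stringsAsFactors = FALSE)
}

.empty_annotation <- function() {
  data.frame(interaction_id = character(), lnc_id = character(),
             target_id = character(), mechanism = character(),
             evidence_chrom = character(), evidence_start = integer(),
             evidence_end = integer(), evidence_strand = character(),
             splice_site_class = character(), stringsAsFactors = FALSE)
}

# is feature row entirely inside the union of region rows (same strand)?
.contained <- function(feature, region) {
  region <- region[region$chrom == feature$chrom &
                     region$strand == feature$strand, , drop = FALSE]
  if (nrow(region) == 0L) return(FALSE)
  left <- IRanges::IRanges(feature$start + 1L, feature$end)
  cover <- IRanges::reduce(IRanges::IRanges(region$start + 1L, region$end))
  sum(IRanges::width(IRanges::intersect(left, cover))) == feature$end -
    feature$start
}

# overlap width of feature with the union of region rows (same strand)
.overlap_width <- function(feature, region) {
  region <- region[region$chrom == feature$chrom &
                     region$strand == feature$strand, , drop = FALSE]
  if (nrow(region) == 0L) return(0L)
  f <- IRanges::IRanges(feature$start + 1L, feature$end)
  cover <- IRanges::reduce(IRanges::IRanges(region$start + 1L, region$end))
  sum(IRanges::width(IRanges::intersect(f, cover)))
}

#' Splice-signal masking candidates
#'
#' For junction-spanning pre-mRNA interactions, keeps every (interaction,
#' CLIP site) pair where the putative splicing-factor binding site lies
#' entirely within the interaction's genomic region on the same strand.
#' Each spanned exon-intron boundary is classified alternative or
#' constitutive from the gene's isoform structure and the classes are
#' attached (comma-separated when several junctions are spanned).
#'
#' @param interactions list of `interaction_record`s (pre-mRNA mode,
#'   already junction-filtered).
#' @param clip_sites BED `data.frame` of CLIP intervals (strand required).
#' @param models named list of all `transcript_model`s (for splice-site
#'   classification).
#' @return annotation `data.frame`.
#' @export
splice_mask_candidates <- function(interactions, clip_sites, models) {
  if (nrow(clip_sites) > 0L && any(!clip_sites$strand %in% c("+", "-")))
    stop("CLIP sites must carry a strand")
  out <- .empty_annotation()
  for (rec in interactions) {
    if (rec$alignment$mode != "pre-mRNA") next
    a <- rec$alignment
    q <- rec$target_model
    junctions <- .premrna_junctions(q)
    spanned <- junctions[junctions > a$target_start &
                           junctions < a$target_end]
    if (length(spanned) == 0L) next
    cls <- vapply(spanned, function(j)
      classify_splice_site(models, q$chrom,
                           premrna_to_genomic(q, j) +
                             if (q$strand == "-") 1L else 0L),
      character(1))
    cls_str <- paste(cls, collapse = ",")
    for (i in seq_len(nrow(clip_sites))) {
      f <- clip_sites[i, , drop = FALSE]
      if (.contained(f, rec$target_genomic))
        out <- rbind(out, .annotation_row(rec, "splice_mask", f, cls_str))
    }
  }
  out
}

#' Classify a splice site as alternative or constitutive
#'
#' A genomic exon boundary is constitutive iff every transcript of the gene
#' whose genomic span covers the position (strictly inside the span) uses
#' it as an exon boundary; otherwise it is alternative. Boundaries are
#' genomic 0-based coordinates lying between two bases (the half-open exon
#' end, or the exon start).
#'
#' @param models named list of `transcript_model`s (the gene's isoforms
#'   are selected automatically).
#' @param chrom chromosome.
#' @param position 0-based genomic boundary coordinate.
#' @return `"alternative"` or `"constitutive"`.
#' @export
classify_splice_site <- function(models, chrom, position) {
  boundary_of <- function(m) {
    ex <- m$exons
    if (nrow(ex) < 2L) return(integer())
    c(ex$end[-nrow(ex)], ex$start[-1L])
  }
  users <- Filter(function(m) m$chrom == chrom &&
                    position %in% boundary_of(m), models)
  if (length(users) == 0L)
    stop("position ", position, " is not an exon boundary of any transcript")
  gene <- users[[1]]$gene_id
  gene_models <- Filter(function(m) m$gene_id == gene, models)
  covering <- Filter(function(m) {
    sp <- tx_span(m)
    position > sp[1] && position < sp[2]
  }, gene_models)
  uses <- vapply(covering, function(m) position %in% boundary_of(m),
                 logical(1))
  if (all(uses)) "constitutive" else "alternative"
}

#' miRNA-site masking candidates
#'
#' Keeps every (mRNA-mode interaction, miRNA site) pair where at least half
#' of the site — `ceiling(site_length / 2)` bases — lies within the
#' interaction's genomic region on the target strand. Sites are expected
#' to be the merged intersection of CLIP-supported and predicted target
#' sites (see [intersect_site_sets()]).
#'
#' @param interactions list of `interaction_record`s (mRNA mode).
#' @param mirna_sites BED `data.frame` of merged miRNA target sites.
#' @return annotation `data.frame`.
#' @export
mirna_mask_candidates <- function(interactions, mirna_sites) {
  if (nrow(mirna_sites) > 0L &&
      any(mirna_sites$end - mirna_sites$start <= 0L))
    stop("zero-length miRNA site")
  out <- .empty_annotation()
  for (rec in interactions) {
    if (rec$alignment$mode != "mRNA") next
    for (i in seq_len(nrow(mirna_sites))) {
      f <- mirna_sites[i, , drop = FALSE]
      len <- f$end - f$start
      if (.overlap_width(f, rec$target_genomic) >= ceiling(len / 2))
        out <- rbind(out, .annotation_row(rec, "mirna_mask", f))
    }
  }
  out
}

#' Intersect CLIP-supported and predicted miRNA site sets
#'
#' Both sets are merged to non-redundant coordinates, then the per-strand
#' common part is returned — the final miRNA-site set checked against
#' lncRNA-mRNA alignments.
#'
#' @param clip_sites,predicted_sites BED `data.frame`s.
#' @return merged BED `data.frame` of the intersection.
#' @export
intersect_site_sets <- function(clip_sites, predicted_sites) {
  intersect_regions(merge_regions(clip_sites),
                    merge_regions(predicted_sites))
}

#' Staufen-mediated decay candidates
#'
#' Keeps every (mRNA-mode interaction, Alu element) pair where the Alu is
#' entirely inside the interaction's genomic region AND entirely inside the
#' target's 3'UTR, for protein-coding targets. Double-stranded
#' 3'UTR structures formed this way are Staufen-1 binding substrates, so
#' such configurations mark the transcript for SMD.
#'
#' @param interactions list of `interaction_record`s (mRNA mode).
#' @param alu_elements BED `data.frame` of Alu/repeat elements.
#' @return annotation `data.frame`.
#' @export
smd_candidates <- function(interactions, alu_elements) {
  out <- .empty_annotation()
  for (rec in interactions) {
    if (rec$alignment$mode != "mRNA") next
    tm <- rec$target_model
    if (tm$biotype != "protein_coding" || is.null(tm$cds)) next
    cds_tx <- .cds_tx(tm)
    if (cds_tx[2] >= tx_length(tm)) next  # no 3'UTR
    utr3 <- merge_regions(project_to_genome(tm, cds_tx[2], tx_length(tm)))
    for (i in seq_len(nrow(alu_elements))) {
      f <- alu_elements[i, , drop = FALSE]
      if (.contained(f, rec$target_genomic) && .contained(f, utr3))
        out <- rbind(out, .annotation_row(rec, "smd", f))
    }
  }
  out
}

#' A-to-I editing candidates
#'
#' Keeps every (mRNA-mode interaction, editing site) pair where the
#' single-base editing position falls inside the interaction's genomic
#' region (half-open: a site at the exclusive end is outside).
#'
#' @param interactions list of `interaction_record`s (mRNA mode).
#' @param editing_sites BED `data.frame` of single-position records
#'   (width 1).
#' @return annotation `data.frame`.
#' @export
editing_candidates <- function(interactions, editing_sites) {
  if (nrow(editing_sites) > 0L &&
      any(editing_sites$end - editing_sites$start != 1L))
    stop("editing sites must be single-base records")
  out <- .empty_annotation()
  for (rec in interactions) {
    if (rec$alignment$mode != "mRNA") next
    for (i in seq_len(nrow(editing_sites))) {
      f <- editing_sites[i, , drop = FALSE]
      if (.contained(f, rec$target_genomic))
        out <- rbind(out, .annotation_row(rec, "editing", f))
    }
  }
  out
}

#' Run all four regulatory filters
#'
#' @param mrna_interactions mRNA-mode `interaction_record`s.
#' @param premrna_interactions junction-spanning pre-mRNA-mode records.
#' @param features list with BED `data.frame`s `clip`, `mirna`, `alu`,
#'   `editing`.
#' @param models named list of all `transcript_model`s.
#' @return annotation `data.frame` over all mechanisms.
#' @export
regulatory_annotations <- function(mrna_interactions, premrna_interactions,
                                   features, models) {
  rbind(
    splice_mask_candidates(premrna_interactions, features$clip, models),
    mirna_mask_candidates(mrna_interactions, features$mirna),
    smd_candidates(mrna_interactions, features$alu),
    editing_candidates(mrna_interactions, features$editing))
}
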