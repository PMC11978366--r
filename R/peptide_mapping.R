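# Placement of MS peptides on the annotated proteome and, failing that, on
# the six-frame translated genome, with per-placement classification.
#
# Hit categories:
#   exonic         one coding block inside one annotated exon
#   junction       >= 2 blocks, i.e. the peptide crosses an exon boundary
#   novel_region   contiguous genomic match outside every same-strand CDS
#   intron_retained contiguous match overlapping an annotated intron
#   ambiguous      multiple genomic placements, or frame/strand discordance
#                  with overlapping annotation
#   unmapped       no placement anywhere

.new_hit <- function(peptide, psm_count, contig, strand, blocks, category,
                     gene_id = NA_character_, mrna_id = NA_character_,
                     extra = list()) {
  c(list(peptide = peptide, psm_count = psm_count, contig = contig,
         strand = strand, blocks = blocks, category = category,
         gene_id = gene_id, mrna_id = mrna_id), extra)
}

# lift a CDS residue interval [aa_s, aa_e] of a model to genomic blocks
.lift_to_blocks <- function(m, aa_s, aa_e) {
  nt_s <- 3L * (aa_s - 1L) + 1L
  nt_e <- 3L * aa_e
  ex <- m$exons
  lens <- ex$end - ex$start + 1L
  cum_end <- cumsum(lens)
  cum_start <- cum_end - lens + 1L
  rows <- which(cum_start <= nt_e & cum_end >= nt_s)
  blocks <- data.frame(contig = character(), start = integer(),
                       end = integer(), strand = character())
  for (i in rows) {
    o1 <- max(nt_s, cum_start[i]) - cum_start[i] + 1L  # local 5' offset
    o2 <- min(nt_e, cum_end[i]) - cum_start[i] + 1L
    if (ex$strand[i] == "+") {
      gs <- ex$start[i] + o1 - 1L; ge <- ex$start[i] + o2 - 1L
    } else {
      gs <- ex$end[i] - o2 + 1L; ge <- ex$end[i] - o1 + 1L
    }
    blocks <- rbind(blocks, data.frame(contig = ex$contig[i], start = gs,
                                       end = ge, strand = ex$strand[i]))
  }
  blocks
}

# spliced proteins of a model list, trailing stop stripped, cached
.model_proteins <- function(models, genome) {
  lapply(models, function(m) sub("\\*$", "", spliced_cds(m, genome)$protein))
}

#' Map one peptide onto annotated gene models
#'
#' Finds every occurrence of the peptide in each model's spliced protein
#' (I and L interchangeable when `il_equivalent`) and lifts it back through
#' the exon chain to genomic coding blocks. Occurrences crossing an exon
#' boundary are classified `junction`, others `exonic`.
#'
#' @param peptide peptide sequence (string) or a one-row peptide record.
#' @param models list of `gene_model`.
#' @param genome named character vector.
#' @param il_equivalent treat I and L as identical (MS cannot distinguish
#'   them). Default TRUE.
#' @param proteins optional precomputed list from internal caches.
#' @param psm_count spectral count carried into the hit records.
#' @return list of hits (possibly empty).
#' @export
map_to_annotated <- function(peptide, models, genome, il_equivalent = TRUE,
                             proteins = NULL, psm_count = 1L) {
  if (is.null(proteins)) proteins <- .model_proteins(models, genome)
  pep_f <- if (il_equivalent) .il_fold(peptide) else peptide
  hits <- list()
  for (k in seq_along(models)) {
    m <- models[[k]]
    prot <- if (il_equivalent) .il_fold(proteins[[k]]) else proteins[[k]]
    occ <- gregexpr(pep_f, prot, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) next
    for (o in as.integer(occ)) {
      aa_s <- o; aa_e <- o + nchar(peptide) - 1L
      blocks <- .lift_to_blocks(m, aa_s, aa_e)
      cat <- if (nrow(blocks) > 1L) "junction" else "exonic"
      hits[[length(hits) + 1L]] <- .new_hit(
        peptide, psm_count, m$contig, m$strand, blocks, cat,
        gene_id = m$gene_id, mrna_id = m$mrna_id,
        extra = list(aa_start = aa_s, aa_end = aa_e))
    }
  }
  hits
}

# six-frame scans for all contigs, cached as a list keyed by contig
.genome_orfs <- function(genome, min_protein_len = 8L) {
  lapply(stats::setNames(names(genome), names(genome)), function(ctg)
    six_frame_scan(genome[[ctg]], min_protein_len, ctg))
}

#' Map one peptide onto the six-frame translated genome
#'
#' Searches every maximal stop-free ORF stretch for the peptide. A placement
#' fully outside every same-strand annotated CDS base is `novel_region`; a
#' placement overlapping an annotated intron of a model on that model's
#' strand is a candidate `intron_retained`; a placement overlapping annotated
#' CDS in a discordant frame, or any placement of a multi-locus peptide, is
#' `ambiguous`.
#'
#' @inheritParams map_to_annotated
#' @param orfs optional precomputed output of the internal six-frame cache.
#' @param min_protein_len minimum ORF stretch length used in the scan.
#' @return list of hits (possibly empty).
#' @export
map_to_genome <- function(peptide, genome, models, il_equivalent = TRUE,
                          orfs = NULL, min_protein_len = 8L, psm_count = 1L) {
  if (is.null(orfs)) orfs <- .genome_orfs(genome, min_protein_len)
  pep_f <- if (il_equivalent) .il_fold(peptide) else peptide
  plen <- nchar(peptide)
  placements <- list()
  for (ctg in names(orfs)) {
    sf <- orfs[[ctg]]
    for (r in seq_len(nrow(sf))) {
      prot <- if (il_equivalent) .il_fold(sf$protein[r]) else sf$protein[r]
      occ <- gregexpr(pep_f, prot, fixed = TRUE)[[1L]]
      if (occ[1L] == -1L) next
      for (o in as.integer(occ)) {
        if (sf$strand[r] == "+") {
          gs <- sf$start[r] + 3L * (o - 1L)
          ge <- gs + 3L * plen - 1L
        } else {
          ge <- sf$end[r] - 3L * (o - 1L)
          gs <- ge - 3L * plen + 1L
        }
        placements[[length(placements) + 1L]] <-
          list(contig = ctg, strand = sf$strand[r], start = gs, end = ge)
      }
    }
  }
  if (!length(placements)) return(list())
  # de-duplicate placements found in several overlapping ORF records
  key <- vapply(placements, function(p)
    paste(p$contig, p$strand, p$start, p$end), character(1))
  placements <- placements[!duplicated(key)]
  multi <- length(placements) > 1L

  hits <- list()
  for (p in placements) {
    cat <- "novel_region"
    ir_gene <- NA_character_; ir_intron <- NA_integer_
    opp <- character()
    for (m in models) {
      ex <- m$exons[m$exons$contig == p$contig, , drop = FALSE]
      if (!nrow(ex)) next
      same <- ex$strand[1L] == p$strand
      ov_exon <- any(.overlaps(ex$start, ex$end, p$start, p$end))
      if (!same && ov_exon) opp <- c(opp, m$gene_id)
      intr <- model_introns(m)
      ov_intron <- FALSE
      if (!is.null(intr)) {
        ii <- intr[intr$contig == p$contig, , drop = FALSE]
        w <- which(.overlaps(ii$start, ii$end, p$start, p$end))
        if (length(w) && same) {
          ov_intron <- TRUE
          ir_gene <- m$gene_id; ir_intron <- ii$index[w[1L]]
        }
      }
      if (same && ov_intron) {
        cat <- "intron_retained"
      } else if (same && ov_exon && cat != "intron_retained") {
        cat <- "ambiguous"  # inside annotated CDS but not found there in frame
      }
    }
    if (multi) cat <- "ambiguous"
    hits[[length(hits) + 1L]] <- .new_hit(
      peptide, psm_count, p$contig, p$strand,
      data.frame(contig = p$contig, start = p$start, end = p$end,
                 strand = p$strand),
      cat, gene_id = ir_gene,
      extra = list(intron_index = ir_intron,
                   opposite_strand_genes = list(opp)))
  }
  hits
}

#' Classify all peptides against annotation and genome
#'
#' Annotated mapping is attempted first; the six-frame genome search runs
#' only for peptides with no annotated hit (or always, in exhaustive mode).
#' Peptides with no placement anywhere yield a single `unmapped` record.
#' Output is deterministic given inputs and config.
#'
#' @param peptides data.frame with `peptide`, `psm_count`, `source`.
#' @param models list of `gene_model`.
#' @param genome named character vector.
#' @param config list; honoured fields `il_equivalent` (default TRUE),
#'   `exhaustive` (default FALSE), `min_protein_len` (default 8).
#' @return list of hits, in peptide-table order.
#' @export
classify_all <- function(peptides, models, genome, config = list()) {
  il <- config$il_equivalent %||% TRUE
  exhaustive <- config$exhaustive %||% FALSE
  mpl <- config$min_protein_len %||% 8L
  proteins <- .model_proteins(models, genome)
  orfs <- NULL
  hits <- list()
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[i]
    psm <- peptides$psm_count[i]
    h <- map_to_annotated(pep, models, genome, il, proteins, psm)
    if (!length(h) || exhaustive) {
      if (is.null(orfs)) orfs <- .genome_orfs(genome, mpl)
      h <- c(h, map_to_genome(pep, genome, models, il, orfs, mpl, psm))
    }
    if (!length(h)) {
      h <- list(.new_hit(pep, psm, NA_character_, NA_character_,
                         data.frame(contig = character(), start = integer(),
                                    end = integer(), strand = character()),
                         "unmapped"))
    }
    hits <- c(hits, h)
  }
  hits
}

#' Summarize hits as a data.frame
#'
#' One row per hit with its span and category; block detail is flattened to
#' a `blocks` count.
#'
#' @param hits list of hits from [classify_all()].
#' @return data.frame.
#' @export
hits_table <- function(hits) {
  do.call(rbind, lapply(hits, function(h) data.frame(
    peptide = h$peptide, psm_count = h$psm_count,
    contig = h$contig, strand = h$strand,
    start = if (nrow(h$blocks)) min(h$blocks$start) else NA_integer_,
    end = if (nrow(h$blocks)) max(h$blocks$end) else NA_integer_,
    n_blocks = nrow(h$blocks), category = h$category,
    gene_id = h$gene_id)))
}
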