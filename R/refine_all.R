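# End-to-end refinement orchestrator. Fixed stage order: integrity checks ->
# peptide mapping -> inversion fixes -> fragment detection -> transcript-
# driven consolidation (merges, cross-contig patches, upstream additions) ->
# peptide-driven consolidation (merges, novel/terminal exons) -> intron
# retention -> ledger. Deterministic given inputs and config; running the
# pipeline on its own output yields an empty ledger.

.default_config <- function(config = list()) {
  defaults <- list(il_equivalent = TRUE, min_peptides = 1L,
                   min_identity = 0.95, min_coverage = 0.9,
                   overlap_tol = 5L, splice_window = 300L,
                   max_merge_gap = 50000L, min_block = 20L,
                   missed_cleavages = 2L, peptide_len = c(7L, 35L),
                   min_protein_len = 8L, exhaustive = FALSE)
  utils::modifyList(defaults, config)
}

.model_ids <- function(models) {
  vapply(models, `[[`, character(1), "gene_id")
}

.exons_equal <- function(a, b) {
  cols <- c("contig", "start", "end", "strand")
  a <- a[, cols]; b <- b[, cols]
  rownames(a) <- NULL; rownames(b) <- NULL
  nrow(a) == nrow(b) && all(a$contig == b$contig) &&
    all(a$start == b$start) && all(a$end == b$end) &&
    all(a$strand == b$strand)
}

# exon chain from a colinear transcript chain plus placed patches, in
# transcript order
.chain_to_exons <- function(chain, patches = NULL) {
  b <- chain$blocks
  rows <- data.frame(mrna_start = b$mrna_start, contig = b$contig,
                     start = b$start, end = b$end, strand = b$strand)
  if (!is.null(patches)) rows <- rbind(rows, patches)
  rows <- rows[order(rows$mrna_start), , drop = FALSE]
  rows[, c("contig", "start", "end", "strand")]
}

#' Refine gene annotations against peptide, protein and transcript evidence
#'
#' Runs the full correction pipeline and returns the refined models, the
#' (possibly assembly-corrected) genome, the correction ledger, unresolved
#' cases, per-gene evidence tiers and a bookkeeping summary.
#'
#' @param genome named character vector of contig sequences.
#' @param models list of `gene_model` (the annotation under review).
#' @param peptides data.frame with `peptide`, `psm_count`, `source`.
#' @param proteins named character vector of full-length protein evidence.
#' @param transcripts named character vector of transcript evidence.
#' @param config list overriding defaults: `il_equivalent` (TRUE),
#'   `min_peptides` (1), `min_identity` (0.95), `min_coverage` (0.9),
#'   `overlap_tol` (5 aa), `splice_window` (300 nt), `max_merge_gap`
#'   (50 kb), `min_block` (20 nt), `min_protein_len` (8 aa).
#' @return object of class `refinement_result`.
#' @export
refine_all <- function(genome, models, peptides, proteins,
                       transcripts = character(), config = list()) {
  cfg <- .default_config(config)
  lapply(models, validate_gene_model)
  working <- models
  records <- list()
  unresolved <- list()
  proteoforms <- list()
  gene_transcripts <- list()   # gene_id -> transcript ids
  inversion_info <- list()     # transcript name -> fixed interval

  # stage 1: integrity audit of the input annotation
  anomalies0 <- unlist(lapply(working, check_model_integrity, genome = genome),
                       recursive = FALSE)

  # stage 2: peptide mapping against the input annotation (audit snapshot)
  hits0 <- classify_all(peptides, working, genome, cfg)

  # stage 3: inversion detection and assembly correction (transcript-driven)
  inversion_affected <- character()
  for (tn in names(transcripts)) {
    ch <- .chain_transcript(transcripts[[tn]], genome, cfg$min_block)
    if (is.null(ch)) next
    ch$chain$mrna <- transcripts[[tn]]
    inv <- detect_inversion(ch$chain, working, ch$contig)
    if (!length(inv)) next
    fix <- correct_inversion(genome, inv[[1L]], working, cfg$min_block)
    if (fix$ok) {
      genome <- fix$genome
      working <- fix$models
      inversion_affected <- union(inversion_affected, inv[[1L]]$gene_ids)
      inversion_info[[tn]] <- fix$interval
    } else {
      unresolved[[length(unresolved) + 1L]] <- list(
        gene_ids = inv[[1L]]$gene_ids,
        reason = "inversion evidence inconsistent after re-orientation")
    }
  }

  # stage 4/5: transcript-driven consolidation
  consumed <- character()
  for (tn in names(transcripts)) {
    ch <- .chain_transcript(transcripts[[tn]], genome, cfg$min_block)
    if (is.null(ch) || !.chain_colinear(ch$chain$blocks)) {
      if (!is.null(ch)) {
        unresolved[[length(unresolved) + 1L]] <- list(
          gene_ids = tn, reason = "transcript chain not colinear")
      }
      next
    }
    patches <- NULL
    patch_failed <- FALSE
    un <- ch$chain$unplaced
    if (!is.null(un)) {
      for (ui in seq_len(nrow(un))) {
        seg <- substr(transcripts[[tn]], un$mrna_start[ui], un$mrna_end[ui])
        if (nchar(seg) < cfg$min_block) next
        pl <- .place_segment(seg, genome, ch$contig)
        if (is.null(pl)) {
          patch_failed <- TRUE
          unresolved[[length(unresolved) + 1L]] <- list(
            gene_ids = tn,
            reason = sprintf(
              "transcript segment %d-%d not recoverable on any contig",
              un$mrna_start[ui], un$mrna_end[ui]))
        } else {
          patches <- rbind(patches, cbind(mrna_start = un$mrna_start[ui],
                                          pl))
        }
      }
    }
    if (patch_failed) next
    exon_rows <- .chain_to_exons(ch$chain, patches)
    assoc_idx <- which(vapply(working, function(m) any(vapply(
      seq_len(nrow(exon_rows)), function(k)
        any(m$exons$contig == exon_rows$contig[k] &
              .overlaps(m$exons$start, m$exons$end,
                        exon_rows$start[k], exon_rows$end[k])),
      logical(1))), logical(1)))
    assoc_idx <- assoc_idx[!(.model_ids(working[assoc_idx]) %in% consumed)]
    if (!length(assoc_idx)) next
    # order associated models along the transcript
    first_block <- vapply(working[assoc_idx], function(m) {
      ks <- which(vapply(seq_len(nrow(exon_rows)), function(k)
        any(m$exons$contig == exon_rows$contig[k] &
              .overlaps(m$exons$start, m$exons$end,
                        exon_rows$start[k], exon_rows$end[k])),
        logical(1)))
      if (length(ks)) min(ks) else NA_integer_
    }, integer(1))
    assoc_idx <- assoc_idx[order(first_block)]
    assoc <- working[assoc_idx]
    ids <- .model_ids(assoc)
    for (gid in ids) {
      gene_transcripts[[gid]] <- union(gene_transcripts[[gid]] %||%
                                         character(), tn)
    }
    if (length(assoc) == 1L && .exons_equal(assoc[[1L]]$exons, exon_rows)) {
      next  # chain confirms the annotation; nothing to correct
    }
    out_id <- ids[1L]
    attrs <- list(evidence_transcript = tn)
    if (length(ids) > 1L) attrs$merged_from <- paste(ids, collapse = ",")
    cand <- tryCatch(gene_model(out_id, exon_rows,
                                mrna_id = paste0(out_id, ".t1"),
                                attrs = attrs),
                     error = function(e) NULL)
    if (is.null(cand)) {
      unresolved[[length(unresolved) + 1L]] <- list(
        gene_ids = ids, reason = "transcript chain yields an invalid model")
      next
    }
    prot <- spliced_cds(cand, genome)$protein
    if (grepl("*", sub("\\*$", "", prot), fixed = TRUE) ||
        !grepl("\\*$", prot)) {
      unresolved[[length(unresolved) + 1L]] <- list(
        gene_ids = ids, reason = "transcript-derived CDS is not clean")
      next
    }
    # identity gate against the best-matching full-length evidence protein
    target_id <- NA_character_
    if (length(proteins)) {
      als <- vapply(names(proteins), function(pid)
        align_proteins(sub("\\*$", "", prot),
                       sub("\\*$", "", proteins[[pid]]))$identity, numeric(1))
      if (max(als) >= cfg$min_identity) target_id <- names(which.max(als))
    }
    class <- if (any(ids %in% inversion_affected)) "inversion_fix"
    else if (length(ids) >= 2L) "merge"
    else if (!is.null(patches)) "cross_contig_patch"
    else if (nrow(exon_rows) > nrow(assoc[[1L]]$exons) &&
               .exons_equal(
                 exon_rows[(nrow(exon_rows) - nrow(assoc[[1L]]$exons) + 1L):
                             nrow(exon_rows), , drop = FALSE],
                 assoc[[1L]]$exons))
      "upstream_exon_addition"
    else "novel_exon"
    if (class == "cross_contig_patch" && nrow(peptides)) {
      # a peptide shared by both sides of the patch is required evidence
      # when peptide data exist for the locus
      bridge <- .patch_bridge_peptides(cand, genome, peptides$peptide,
                                       cfg$il_equivalent)
      locus_has_peps <- any(vapply(peptides$peptide, function(p)
        grepl(.il_fold(p), .il_fold(sub("\\*$", "", prot)), fixed = TRUE),
        logical(1)))
      if (locus_has_peps && !length(bridge)) {
        unresolved[[length(unresolved) + 1L]] <- list(
          gene_ids = ids,
          reason = "no peptide shared by both sides of the assembly gap")
        next
      }
    }
    detail <- sprintf("transcript %s chain: %d exon(s)%s%s", tn,
                      nrow(exon_rows),
                      if (!is.null(patches))
                        sprintf("; %d segment(s) recovered on %s",
                                nrow(patches),
                                paste(unique(patches$contig), collapse = ","))
                      else "",
                      if (class == "inversion_fix")
                        sprintf("; inverted block %d-%d re-oriented",
                                inversion_info[[tn]][1L],
                                inversion_info[[tn]][2L]) else "")
    if (!is.na(target_id)) {
      detail <- paste0(detail, sprintf("; reconstructs %s", target_id))
    }
    cand$attrs$corrected <- class
    cand$attrs$evidence_tier <- if (nrow(peptides) &&
                                      .gene_has_peptide(cand, genome,
                                                        peptides$peptide,
                                                        cfg$il_equivalent))
      "protein" else "transcript"
    records[[length(records) + 1L]] <- .correction(
      class, ids, cand,
      evidence = list(transcript = tn, full_length_id = target_id),
      detail = detail)
    consumed <- c(consumed, ids)
    working <- c(working[-assoc_idx], list(cand))
  }

  # stage 6: peptide-driven consolidation (fragment maps + novel exons)
  hits1 <- classify_all(peptides, working, genome, cfg)
  clusters <- .cluster_novel_hits(hits1)
  unmapped <- unique(vapply(
    Filter(function(h) h$category == "unmapped", hits1),
    `[[`, character(1), "peptide"))
  if (length(proteins)) {
    maps <- detect_fragment_relation(working, proteins, genome,
                                     list(min_identity = cfg$min_identity,
                                          min_coverage = cfg$min_coverage,
                                          overlap_tol = cfg$overlap_tol))
    models_by_id <- stats::setNames(working, .model_ids(working))
    cfg2 <- cfg
    cfg2$targets <- as.list(proteins)
    for (map in maps) {
      if (any(map$placements$gene_id %in% consumed)) next
      res <- .assemble_from_fragments(map, models_by_id, clusters, genome,
                                      unmapped, peptides$peptide, cfg2)
      if (is.null(res)) next
      if (!is.null(res$unresolved)) {
        unresolved[[length(unresolved) + 1L]] <- list(
          gene_ids = res$input_ids, reason = res$unresolved)
        next
      }
      ids <- unique(res$record$input_gene_ids)
      drop_idx <- which(.model_ids(working) %in% ids)
      working <- c(working[-drop_idx], list(res$model))
      records[[length(records) + 1L]] <- res$record
      consumed <- c(consumed, ids)
    }
  }

  # stage 7: intron-retention proteoforms
  hits2 <- classify_all(peptides, working, genome, cfg)
  ir <- Filter(function(h) h$category == "intron_retained", hits2)
  ir_genes <- unique(vapply(ir, `[[`, character(1), "gene_id"))
  for (gid in ir_genes) {
    midx <- which(.model_ids(working) == gid)
    if (!length(midx)) next
    res <- call_intron_retention(working[[midx[1L]]],
                                 ir[vapply(ir, `[[`, character(1),
                                           "gene_id") == gid],
                                 genome)
    if (is.null(res)) next
    if (!is.null(res$unresolved)) {
      unresolved[[length(unresolved) + 1L]] <- list(gene_ids = gid,
                                                    reason = res$unresolved)
      next
    }
    working <- c(working, list(res$retained_model))
    proteoforms[[gid]] <- res$pair
    records[[length(records) + 1L]] <- res$record
  }

  # stage 8: final audit, unresolved flagging, evidence tiers, summary
  hits_final <- classify_all(peptides, working, genome, cfg)
  final_anoms <- lapply(working, check_model_integrity, genome = genome)
  for (k in seq_along(working)) {
    if (length(final_anoms[[k]])) {
      working[[k]]$attrs$status <- "putative_fragment"
      unresolved[[length(unresolved) + 1L]] <- list(
        gene_ids = working[[k]]$gene_id,
        reason = paste("unrepaired:", paste(
          vapply(final_anoms[[k]], `[[`, character(1), "class"),
          collapse = ",")))
    }
  }
  evidence <- .evidence_tiers(working, hits_final, gene_transcripts)
  ledger <- ledger_table(records)
  summary <- summarize_refinement(ledger, evidence,
                                  length(unique(.model_ids(models))))

  structure(list(
    models = working, genome = genome, records = records, ledger = ledger,
    unresolved = unresolved, proteoforms = proteoforms,
    input_anomalies = anomalies0, input_hits = hits0, hits = hits_final,
    evidence = evidence, summary = summary, config = cfg),
    class = "refinement_result")
}

# peptides mapping across the contig-change junction of a patched model
.patch_bridge_peptides <- function(model, genome, peptides, il = TRUE) {
  ex <- model$exons
  chg <- which(ex$contig[-1L] != ex$contig[-nrow(ex)])
  if (!length(chg)) return(character())
  prot <- sub("\\*$", "", spliced_cds(model, genome)$protein)
  prot_f <- if (il) .il_fold(prot) else prot
  lens <- ex$end - ex$start + 1L
  bounds <- cumsum(lens)[chg]
  out <- character()
  for (pep in peptides) {
    p <- if (il) .il_fold(pep) else pep
    occ <- gregexpr(p, prot_f, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) next
    for (o in as.integer(occ)) {
      nt_s <- 3L * (o - 1L) + 1L
      nt_e <- 3L * (o + nchar(pep) - 1L)
      if (any(bounds >= nt_s & bounds < nt_e)) out <- c(out, pep)
    }
  }
  unique(out)
}

.gene_has_peptide <- function(model, genome, peptides, il = TRUE) {
  prot <- sub("\\*$", "", spliced_cds(model, genome)$protein)
  prot_f <- if (il) .il_fold(prot) else prot
  any(vapply(peptides, function(p)
    grepl(if (il) .il_fold(p) else p, prot_f, fixed = TRUE), logical(1)))
}

.evidence_tiers <- function(models, hits, gene_transcripts) {
  ids <- unique(.model_ids(models))
  rows <- lapply(ids, function(gid) {
    status <- "gene"
    for (m in models) {
      if (m$gene_id == gid && identical(m$attrs$status, "putative_fragment")) {
        status <- "putative_fragment"
      }
    }
    peps <- unique(vapply(Filter(function(h)
      !is.na(h$gene_id) && h$gene_id == gid &&
        h$category %in% c("exonic", "junction"), hits),
      `[[`, character(1), "peptide"))
    trs <- gene_transcripts[[gid]] %||% character()
    assign_evidence_tier(gid, n_unique_peptides = length(peps),
                         transcript_ids = trs, status = status)
  })
  do.call(rbind, rows)
}

#' Ledger of correction records as a data.frame
#'
#' @param records list of correction records from [refine_all()].
#' @return data.frame with one row per record: `class`, `input_gene_ids`,
#'   `output_gene_id`, `output_mrna_id`, `n_inputs`, `detail`.
#' @export
ledger_table <- function(records) {
  if (!length(records)) {
    return(data.frame(class = character(), input_gene_ids = character(),
                      output_gene_id = character(),
                      output_mrna_id = character(), n_inputs = integer(),
                      detail = character()))
  }
  do.call(rbind, lapply(records, function(r) data.frame(
    class = r$class,
    input_gene_ids = paste(r$input_gene_ids, collapse = ","),
    output_gene_id = r$output_model$gene_id,
    output_mrna_id = r$output_model$mrna_id,
    n_inputs = length(unique(r$input_gene_ids)),
    detail = r$detail)))
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf(
    "refinement_result: %d model(s) in -> %d out; %d correction record(s), %d unresolved\n",
    x$summary$n_genes_before, length(x$models), nrow(x$ledger),
    length(x$unresolved)))
  if (nrow(x$ledger)) {
    print(x$ledger[, c("class", "input_gene_ids", "output_gene_id")])
  }
  invisible(x)
}

#' Write refinement outputs to a directory
#'
#' Emits refined.gff3, ledger.tsv, hits.bed, anomalies.tsv, evidence.tsv and
#' report.json.
#'
#' @param result a `refinement_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_refinement <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(result$models, file.path(dir, "refined.gff3"))
  utils::write.table(result$ledger, file.path(dir, "ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_hits_bed(result$hits, file.path(dir, "hits.bed"))
  utils::write.table(anomaly_table(result$input_anomalies),
                     file.path(dir, "anomalies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$evidence, file.path(dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    summary = unclass(result$summary),
    ledger = result$ledger,
    unresolved = lapply(result$unresolved, function(u)
      list(gene_ids = u$gene_ids, reason = u$reason)),
    proteoforms = result$proteoforms)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
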