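# Application of corrections: merging fragmented models, inferring novel
# exons from peptide/transcript evidence, patching cross-contig assembly
# gaps, correcting inverted blocks, adding upstream exons and calling
# intron-retention proteoforms. Every applied correction is written to a
# ledger of CorrectionRecords.

.correction <- function(class, input_gene_ids, model, evidence = list(),
                        detail = "") {
  stopifnot(class %in% c("merge", "novel_exon", "terminal_exon_addition",
                         "misclassified_exon_removal", "cross_contig_patch",
                         "inversion_fix", "upstream_exon_addition",
                         "intron_retention"))
  list(class = class, input_gene_ids = input_gene_ids, output_model = model,
       evidence = evidence, detail = detail)
}

# ---- strand-aware splice-boundary candidates -------------------------------

# genomic positions usable as an exon 5' start: coding-strand AG immediately
# upstream, searched within `window` nt 5' of `from`. A small 3' slack (one
# codon or two) absorbs peptide placements whose reading frame overhangs the
# supported interval by a base or two.
.candidate_acceptors <- function(genome, contig, strand, from, window,
                                 slack = 9L) {
  g <- genome[[contig]]
  if (strand == "+") {
    lo <- max(3L, from - window)
    ps <- seq(lo, min(nchar(g), from + slack))
    ps[substring(g, ps - 2L, ps - 1L) == "AG"]
  } else {
    hi <- min(nchar(g) - 2L, from + window)
    ps <- seq(max(3L, from - slack), hi)
    ps[substring(g, ps + 1L, ps + 2L) == "CT"]
  }
}

# genomic positions usable as an exon 3' end: coding-strand GT immediately
# downstream, searched within `window` nt 3' of `from` (with a small 5'
# slack back into the supported interval)
.candidate_donors <- function(genome, contig, strand, from, window,
                              slack = 9L) {
  g <- genome[[contig]]
  if (strand == "+") {
    hi <- min(nchar(g) - 2L, from + window)
    ps <- seq(max(3L, from - slack), hi)
    ps[substring(g, ps + 1L, ps + 2L) == "GT"]
  } else {
    lo <- max(3L, from - window)
    ps <- seq(lo, min(nchar(g) - 2L, from + slack))
    ps[substring(g, ps - 2L, ps - 1L) == "AC"]
  }
}

# does any of `peptides` map across the boundary between `left_cds` (frame-0
# coding sequence ending at the junction) and `right_seq` (coding-strand
# continuation)?
.peptide_crosses <- function(left_cds, right_seq, peptides,
                             il_equivalent = TRUE) {
  if (!length(peptides)) return(FALSE)
  full <- paste0(left_cds, right_seq)
  prot <- dna_translate(full, 0L)
  if (il_equivalent) prot <- .il_fold(prot)
  B <- nchar(left_cds)
  for (pep in peptides) {
    p <- if (il_equivalent) .il_fold(pep) else pep
    occ <- gregexpr(p, prot, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) next
    for (o in as.integer(occ)) {
      nt_s <- 3L * (o - 1L) + 1L
      nt_e <- 3L * (o + nchar(pep) - 1L)
      if (nt_s <= B && nt_e >= B + 1L) return(TRUE)
    }
  }
  FALSE
}

# ---- novel exon inference --------------------------------------------------

# cluster novel_region hits into candidate exon support intervals; hits
# overlapping an opposite-strand annotated exon (re-strand evidence) are
# clustered apart from plain novel-region hits so a hidden exon and a
# wrong-strand neighbour are not fused into one candidate
.cluster_novel_hits <- function(hits, max_gap = 60L) {
  nov <- Filter(function(h) h$category == "novel_region", hits)
  if (!length(nov)) return(list())
  key <- vapply(nov, function(h)
    paste(h$contig, h$strand,
          paste(sort(h$opposite_strand_genes[[1L]] %||% character()),
                collapse = "+")), character(1))
  out <- list()
  for (k in unique(key)) {
    hs <- nov[key == k]
    ints <- data.frame(
      start = vapply(hs, function(h) min(h$blocks$start), integer(1)),
      end = vapply(hs, function(h) max(h$blocks$end), integer(1)))
    o <- order(ints$start)
    hs <- hs[o]; ints <- ints[o, , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      ints$start[-1L] > cummax(ints$end[-nrow(ints)]) + max_gap)))
    for (gidx in unique(grp)) {
      sel <- grp == gidx
      out[[length(out) + 1L]] <- list(
        contig = hs[[1L]]$contig, strand = hs[[1L]]$strand,
        start = min(ints$start[sel]), end = max(ints$end[sel]),
        peptides = unique(vapply(hs[sel], `[[`, character(1), "peptide")),
        opp_genes = unique(unlist(lapply(hs[sel], function(h)
          h$opposite_strand_genes[[1L]] %||% character()))))
    }
  }
  out
}

#' Infer a novel exon from clustered novel-region peptide hits
#'
#' The peptide-supported interval is extended outward to the nearest
#' canonical acceptor (5') and donor (3') within `window`; for a terminal
#' exon the 3' end runs to the first in-frame stop codon instead. When
#' several boundaries are compatible, junction-spanning peptides (supplied
#' via the refinement orchestrator) are what pins them exactly; this
#' standalone heuristic reports the nearest candidates.
#'
#' @param hits novel-region hits sharing one contig and strand.
#' @param genome named character vector.
#' @param window boundary search window in nt (default 300).
#' @param terminal if TRUE, extend 3' to the first in-frame stop codon
#'   (frame taken from the supporting hits) instead of a donor site.
#' @return data.frame with one candidate exon (`contig`, `start`, `end`,
#'   `strand`) or zero rows if no canonical boundary is reachable.
#' @export
infer_novel_exon <- function(hits, genome, window = 300L, terminal = FALSE) {
  cl <- .cluster_novel_hits(hits, max_gap = window)
  if (length(cl) != 1L) {
    stop("hits must form a single cluster on one contig/strand; got ",
         length(cl))
  }
  cl <- cl[[1L]]
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character())
  p5 <- if (cl$strand == "+") cl$start else cl$end
  acc <- .candidate_acceptors(genome, cl$contig, cl$strand, p5, window)
  acc <- if (cl$strand == "+") acc[acc <= p5] else acc[acc >= p5]
  if (!length(acc)) return(empty)
  start5 <- if (cl$strand == "+") max(acc) else min(acc)
  p3 <- if (cl$strand == "+") cl$end else cl$start
  if (terminal) {
    end3 <- .extend_to_stop(genome, cl$contig, cl$strand, start5, p3)
    if (is.na(end3)) return(empty)
  } else {
    don <- .candidate_donors(genome, cl$contig, cl$strand, p3, window)
    don <- if (cl$strand == "+") don[don >= p3] else don[don <= p3]
    if (!length(don)) return(empty)
    end3 <- if (cl$strand == "+") min(don) else max(don)
  }
  if (cl$strand == "+") {
    data.frame(contig = cl$contig, start = start5, end = end3, strand = "+")
  } else {
    data.frame(contig = cl$contig, start = end3, end = start5, strand = "-")
  }
}

# first in-frame stop codon at/after `from` (transcription direction), with
# frame anchored at exon 5' start `start5`; returns the genomic coordinate
# of the stop codon's last base, or NA
.extend_to_stop <- function(genome, contig, strand, start5, from,
                            max_scan = 1500L) {
  g <- genome[[contig]]
  if (strand == "+") {
    seq0 <- substr(g, start5, min(nchar(g), from + max_scan))
  } else {
    seq0 <- revcomp(substr(g, max(1L, from - max_scan), start5))
  }
  prot <- dna_translate(seq0, 0L)
  stop_at <- regexpr("*", prot, fixed = TRUE)
  if (stop_at == -1L) return(NA_integer_)
  nt_off <- 3L * as.integer(stop_at)   # offset of stop codon end within seq0
  if (strand == "+") start5 + nt_off - 1L else start5 - nt_off + 1L
}

# ---- transcript-driven corrections -----------------------------------------

# pick the contig carrying the transcript and chain it; cheap k-mer
# prefilter avoids chaining against unrelated contigs
.chain_transcript <- function(mrna, genome, min_block = 20L) {
  probes <- unique(vapply(
    pmax(1L, round(seq(1, nchar(mrna) - min_block, length.out = 3L))),
    function(q) substr(mrna, q, q + min_block - 1L), character(1)))
  best <- NULL
  for (ctg in names(genome)) {
    fwd <- genome[[ctg]]
    hit <- any(vapply(probes, function(p)
      grepl(p, fwd, fixed = TRUE) || grepl(revcomp(p), fwd, fixed = TRUE),
      logical(1)))
    if (!hit) next
    ch <- spliced_align_transcript(mrna, fwd, ctg, min_block)
    placed <- if (is.null(ch$blocks)) 0L else
      sum(ch$blocks$mrna_end - ch$blocks$mrna_start + 1L)
    if (is.null(best) || placed > best$placed) {
      best <- list(contig = ctg, chain = ch, placed = placed)
    }
  }
  best
}

# place an unplaced mRNA segment on some other contig by full-length exact
# match (either strand); NULL if not found
.place_segment <- function(seg, genome, exclude_contig) {
  for (ctg in setdiff(names(genome), exclude_contig)) {
    fwd <- genome[[ctg]]
    rcv <- revcomp(fwd)
    L <- nchar(fwd)
    hit <- .max_prefix_match(seg, 1L, fwd, rcv, L, nchar(seg),
                             list(plus = 0L, minus = 0L))
    if (!is.null(hit) && hit$len == nchar(seg)) {
      return(data.frame(contig = ctg, start = hit$start, end = hit$end,
                        strand = hit$strand))
    }
  }
  NULL
}

# blocks strand/position-colinear (one strand, monotone in transcription)?
.chain_colinear <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) return(FALSE)
  for (ctg in unique(blocks$contig)) {
    b <- blocks[blocks$contig == ctg, , drop = FALSE]
    if (length(unique(b$strand)) > 1L) return(FALSE)
    if (nrow(b) > 1L) {
      mono <- if (b$strand[1L] == "+") all(diff(b$start) > 0) else
        all(diff(b$start) < 0)
      if (!mono) return(FALSE)
    }
  }
  TRUE
}

#' Correct an inverted assembly block
#'
#' Reverse-complements the flagged genomic interval (restoring the assembly
#' the evidence implies), remaps the exons of every model inside the
#' interval through the inversion and flips their strand. Both the flagged
#' interval and its complement-side alternative are tried; the orientation
#' whose re-chained transcript becomes strand-consistent and colinear wins.
#'
#' @param genome named character vector.
#' @param anomaly inversion anomaly from [detect_inversion()].
#' @param models list of `gene_model`.
#' @param min_block exact-match block size for re-chaining.
#' @return list with `genome`, `models`, `interval`, `ok` and (when `ok`)
#'   `chain`, the colinear re-chained transcript.
#' @export
correct_inversion <- function(genome, anomaly, models, min_block = 20L) {
  ev <- anomaly$evidence
  ctg <- ev$contig
  blocks <- ev$chain$blocks
  strands <- unique(blocks$strand)
  candidates <- lapply(strands, function(s) {
    b <- blocks[blocks$strand == s, , drop = FALSE]
    c(min(b$start), max(b$end))
  })
  # try the flagged (minority) interval first
  ord <- order(vapply(candidates, diff, numeric(1)))
  first <- which(vapply(candidates, function(iv)
    identical(iv, ev$interval), logical(1)))
  if (length(first)) ord <- c(first, setdiff(ord, first))
  mrna <- ev$chain$mrna %||% NULL
  for (iv in candidates[ord]) {
    g2 <- genome
    g <- g2[[ctg]]
    g2[[ctg]] <- paste0(substr(g, 1L, iv[1L] - 1L),
                        revcomp(substr(g, iv[1L], iv[2L])),
                        substr(g, iv[2L] + 1L, nchar(g)))
    remapped <- lapply(models, function(m) {
      sel <- m$exons$contig == ctg &
        m$exons$start >= iv[1L] & m$exons$end <= iv[2L]
      if (!any(sel)) return(m)
      ex <- m$exons
      s <- ex$start[sel]; e <- ex$end[sel]
      ex$start[sel] <- iv[1L] + iv[2L] - e
      ex$end[sel] <- iv[1L] + iv[2L] - s
      ex$strand[sel] <- ifelse(ex$strand[sel] == "+", "-", "+")
      m$exons <- ex
      m$strand <- ex$strand[1L]
      m
    })
    ok <- TRUE
    if (!is.null(mrna)) {
      ch <- spliced_align_transcript(mrna, g2[[ctg]], ctg, min_block)
      ok <- .chain_colinear(ch$blocks)
      if (ok) {
        return(list(genome = g2, models = remapped, interval = iv, ok = TRUE,
                    chain = ch))
      }
    } else {
      return(list(genome = g2, models = remapped, interval = iv, ok = TRUE))
    }
  }
  list(genome = genome, models = models, interval = ev$interval, ok = FALSE)
}

#' Add missing upstream exons from a transcript chain
#'
#' @param model the annotated (truncated) `gene_model`.
#' @param chain_exons exon data.frame derived from a colinear transcript
#'   chain covering the model and extending 5' of it.
#' @param genome named character vector.
#' @return list with `model` (extended) and `record`, or `NULL` when the
#'   chain does not extend the model.
#' @export
add_upstream_exons <- function(model, chain_exons, genome) {
  if (.exons_equal(model$exons, chain_exons)) {
    return(NULL)
  }
  new_m <- gene_model(model$gene_id, chain_exons, mrna_id = model$mrna_id,
                      attrs = model$attrs)
  fl <- model_flags(new_m, genome)
  n_added <- nrow(chain_exons) - nrow(model$exons)
  new_m$attrs$corrected <- "upstream_exon_addition"
  if (!fl$has_start) new_m$attrs$has_start <- "false"
  rec <- .correction("upstream_exon_addition", model$gene_id, new_m,
                     detail = sprintf("%d upstream exon(s) added%s", n_added,
                                      if (!fl$has_start)
                                        "; CDS still lacks ATG" else ""))
  list(model = new_m, record = rec, has_start = fl$has_start)
}

#' Patch a model across an assembly gap onto a donor contig
#'
#' @param model annotated model truncated by the gap.
#' @param chain_exons full exon chain (transcript blocks plus the placed
#'   segment on the donor contig), transcription order.
#' @param genome named character vector.
#' @param bridge_peptides peptides that map across the patched junction
#'   (required evidence when peptide data exist for the locus).
#' @return list with `model` and `record`.
#' @export
patch_cross_contig <- function(model, chain_exons, genome,
                               bridge_peptides = character()) {
  new_m <- gene_model(model$gene_id, chain_exons, mrna_id = model$mrna_id,
                      attrs = model$attrs)
  new_m$attrs$corrected <- "cross_contig_patch"
  donor <- setdiff(unique(chain_exons$contig), model$contig)
  rec <- .correction("cross_contig_patch", model$gene_id, new_m,
                     evidence = list(bridge_peptides = bridge_peptides),
                     detail = sprintf("segment recovered on %s",
                                      paste(donor, collapse = ",")))
  list(model = new_m, record = rec)
}

# ---- peptide-driven merge / terminal repair --------------------------------

# Assemble a corrected model from fragment placements plus novel-exon and
# re-strand elements, pinning unknown boundaries with junction-spanning
# peptides. Returns list(model, record) or list(unresolved = reason).
.assemble_from_fragments <- function(map, models_by_id, clusters, genome,
                                     unmapped_peptides, all_peptides, config) {
  window <- config$splice_window %||% 300L
  il <- config$il_equivalent %||% TRUE
  min_id <- config$min_identity %||% 0.95
  target <- sub("\\*$", "", config$targets[[map$full_length_id]])
  target_f <- .il_fold(target)

  pieces <- list()
  input_ids <- character()
  removed <- character()
  for (ri in seq_len(nrow(map$placements))) {
    pr <- map$placements[ri, ]
    m <- models_by_id[[pr$gene_id]]
    ex <- m$exons[seq_len(pr$kept_exons), , drop = FALSE]
    if (pr$trimmed_exons > 0L) {
      removed <- c(removed, sprintf("%s exon(s) %s", pr$gene_id,
                                    paste(pr$kept_exons + seq_len(pr$trimmed_exons),
                                          collapse = ",")))
    }
    pieces[[length(pieces) + 1L]] <- list(
      kind = "fragment", gene_id = pr$gene_id, exons = ex,
      span = c(pr$span_start, pr$span_end))
    input_ids <- c(input_ids, pr$gene_id)
  }
  strand <- pieces[[1L]]$exons$strand[1L]

  # associate novel/re-strand clusters: same contig as some piece, peptides
  # contained in the target protein
  assoc <- Filter(function(cl) {
    on_piece_contig <- any(vapply(pieces, function(p)
      cl$contig %in% p$exons$contig, logical(1)))
    peps_in_target <- all(vapply(cl$peptides, function(p)
      grepl(.il_fold(p), target_f, fixed = TRUE), logical(1)))
    on_piece_contig && length(cl$peptides) >= (config$min_peptides %||% 1L) &&
      peps_in_target
  }, clusters)
  if (!length(assoc) && length(pieces) < 2L && !length(removed)) {
    return(NULL)  # nothing to do for this target
  }

  elements <- pieces
  for (cl in assoc) {
    if (length(cl$opp_genes)) {
      # wrong-strand model: adopt its exon coordinates on the evidence strand
      gid <- cl$opp_genes[1L]
      om <- models_by_id[[gid]]
      if (is.null(om)) next
      ex <- om$exons
      ex$strand <- cl$strand
      if (cl$strand == "-") ex <- ex[order(-ex$start), , drop = FALSE] else
        ex <- ex[order(ex$start), , drop = FALSE]
      elements[[length(elements) + 1L]] <- list(
        kind = "restrand", gene_id = gid, exons = ex, cluster = cl)
      input_ids <- c(input_ids, gid)
    } else {
      elements[[length(elements) + 1L]] <- list(
        kind = "novel", gene_id = NA_character_, cluster = cl)
    }
  }

  # order elements along transcription: genomic order within the shared
  # contig (strand-aware), target-span order across contigs
  el_pos <- vapply(elements, function(el) {
    if (!is.null(el$exons)) {
      p <- if (strand == "+") min(el$exons$start) else -max(el$exons$end)
    } else {
      p <- if (strand == "+") el$cluster$start else -el$cluster$end
    }
    p
  }, numeric(1))
  multi_contig <- length(unique(unlist(lapply(elements, function(el)
    if (!is.null(el$exons)) el$exons$contig else el$cluster$contig)))) > 1L
  if (multi_contig) {
    span_pos <- vapply(elements, function(el)
      if (!is.null(el$span)) el$span[1L] else NA_real_, numeric(1))
    ord <- order(ifelse(is.na(span_pos), el_pos, span_pos))
  } else {
    ord <- order(el_pos)
  }
  elements <- elements[ord]

  # resolve boundaries left to right
  exon_rows <- NULL
  cds_so_far <- ""
  for (ei in seq_along(elements)) {
    el <- elements[[ei]]
    if (el$kind != "novel") {
      exon_rows <- rbind(exon_rows, el$exons)
      cds_so_far <- paste0(cds_so_far, spliced_cds(
        gene_model("tmp", el$exons), genome)$mrna)
      next
    }
    cl <- el$cluster
    p5 <- if (strand == "+") cl$start else cl$end
    acc <- .candidate_acceptors(genome, cl$contig, strand, p5, window)
    # candidate 5' starts validated by a junction peptide against the chain
    # assembled so far
    acc_ok <- integer()
    for (s5 in sort(acc, decreasing = (strand == "+"))) {
      right <- if (strand == "+")
        seq_fetch(genome, cl$contig, s5,
                  min(nchar(genome[[cl$contig]]), s5 + 104L), "+")
      else
        seq_fetch(genome, cl$contig, max(1L, s5 - 104L), s5, "-")
      if (.peptide_crosses(cds_so_far, right, unmapped_peptides, il)) {
        acc_ok <- c(acc_ok, s5)
        break   # nearest validated acceptor (candidates scanned inside-out)
      }
    }
    if (!length(acc_ok)) {
      return(list(unresolved = sprintf(
        "novel exon near %s:%d-%d: 5' boundary unsupported by junction peptides",
        cl$contig, cl$start, cl$end), input_ids = input_ids))
    }
    s5 <- acc_ok[1L]
    terminal <- ei == length(elements)
    if (terminal) {
      p3 <- if (strand == "+") cl$end else cl$start
      e3 <- .extend_to_stop(genome, cl$contig, strand,
                            .novel_frame_anchor(cds_so_far, s5, strand), p3)
      if (is.na(e3)) {
        return(list(unresolved = "terminal novel exon: no in-frame stop",
                    input_ids = input_ids))
      }
    } else {
      # 3' end pinned against the next element's known 5' context
      nxt <- elements[[ei + 1L]]
      nxt_seq <- spliced_cds(gene_model("tmp", nxt$exons), genome)$mrna
      nxt_ctx <- substr(nxt_seq, 1L, 105L)
      p3 <- if (strand == "+") cl$end else cl$start
      don <- .candidate_donors(genome, cl$contig, strand, p3, window)
      e3 <- NA_integer_
      for (d in sort(don, decreasing = (strand == "-"))) {
        left_ext <- if (strand == "+")
          seq_fetch(genome, cl$contig, s5, d, "+")
        else seq_fetch(genome, cl$contig, d, s5, "-")
        if (.peptide_crosses(paste0(cds_so_far, left_ext), nxt_ctx,
                             unmapped_peptides, il)) {
          e3 <- d
          break
        }
      }
      if (is.na(e3)) {
        return(list(unresolved = sprintf(
          "novel exon near %s:%d-%d: 3' boundary unsupported by junction peptides",
          cl$contig, cl$start, cl$end), input_ids = input_ids))
      }
    }
    row <- if (strand == "+")
      data.frame(contig = cl$contig, start = s5, end = e3, strand = "+")
    else data.frame(contig = cl$contig, start = e3, end = s5, strand = "-")
    exon_rows <- rbind(exon_rows, row)
    cds_so_far <- paste0(cds_so_far, seq_fetch(
      genome, cl$contig, row$start, row$end, strand))
  }

  out_id <- input_ids[1L]
  attrs <- list()
  if (length(input_ids) > 1L) {
    attrs$merged_from <- paste(unique(input_ids), collapse = ",")
  }
  cand <- tryCatch(gene_model(out_id, exon_rows,
                              mrna_id = paste0(out_id, ".t1"), attrs = attrs),
                   error = function(e) NULL)
  if (is.null(cand)) {
    return(list(unresolved = "assembled exon chain is not a valid model",
                input_ids = input_ids))
  }
  prot <- spliced_cds(cand, genome)$protein
  if (grepl("*", sub("\\*$", "", prot), fixed = TRUE)) {
    return(list(unresolved = "merged CDS contains an internal stop",
                input_ids = input_ids))
  }
  if (!grepl("\\*$", prot)) {
    return(list(unresolved = "merged CDS lacks a stop codon",
                input_ids = input_ids))
  }
  al <- align_proteins(sub("\\*$", "", prot), target)
  if (al$identity < min_id) {
    return(list(unresolved = sprintf(
      "merged protein identity %.3f below threshold vs %s", al$identity,
      map$full_length_id), input_ids = input_ids))
  }
  # bridging-evidence requirement: at least one peptide must map across a
  # junction of the corrected model when peptide data exist for the locus
  locus_peps <- all_peptides[vapply(all_peptides, function(p)
    grepl(.il_fold(p), target_f, fixed = TRUE), logical(1))]
  if (length(locus_peps)) {
    jhits <- map_to_annotated_any_junction(cand, genome, locus_peps, il)
    if (!jhits) {
      return(list(unresolved = "no junction-spanning peptide supports the merge",
                  input_ids = input_ids))
    }
  }
  n_novel <- sum(vapply(elements, function(el) el$kind == "novel", logical(1)))
  class <- if (length(unique(input_ids)) >= 2L) "merge" else
    if (n_novel > 0L || length(removed)) "terminal_exon_addition" else
      "novel_exon"
  detail <- paste(c(
    sprintf("reconstructs %s (identity %.3f, coverage %.3f)",
            map$full_length_id, al$identity, al$coverage_target),
    if (n_novel) sprintf("%d novel exon(s) inferred", n_novel),
    if (length(removed)) paste("misclassified exon removed:", removed),
    if (is_cross_contig(cand)) "cross-contig part retained"),
    collapse = "; ")
  cand$attrs$corrected <- class
  list(model = cand,
       record = .correction(class, unique(input_ids), cand,
                            evidence = list(full_length_id = map$full_length_id,
                                            identity = al$identity),
                            detail = detail))
}

# frame anchor for terminal-stop extension: the genomic 5' start of the
# terminal exon (frame 0 of the continuing CDS); cds_so_far has already been
# assembled up to the junction, so the anchor is simply s5 shifted so that
# codons continue in frame
.novel_frame_anchor <- function(cds_so_far, s5, strand) {
  phi <- nchar(cds_so_far) %% 3L
  if (strand == "+") s5 + (3L - phi) %% 3L else s5 - (3L - phi) %% 3L
}

# TRUE if any peptide maps onto `model` as a junction-spanning occurrence
map_to_annotated_any_junction <- function(model, genome, peptides, il) {
  prot <- sub("\\*$", "", spliced_cds(model, genome)$protein)
  prot_f <- if (il) .il_fold(prot) else prot
  lens <- model$exons$end - model$exons$start + 1L
  bounds <- cumsum(lens)
  for (pep in peptides) {
    p <- if (il) .il_fold(pep) else pep
    occ <- gregexpr(p, prot_f, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) next
    for (o in as.integer(occ)) {
      nt_s <- 3L * (o - 1L) + 1L
      nt_e <- 3L * (o + nchar(pep) - 1L)
      if (any(bounds[-length(bounds)] >= nt_s &
                bounds[-length(bounds)] < nt_e)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Merge fragmented gene models guided by a fragment map
#'
#' Builds a single model from the exon chains of the fragments (ordered
#' along the full-length evidence protein), interleaving novel exons
#' inferred from unassigned peptide hits and absorbing wrong-strand models
#' whose coordinates the evidence re-strands. Boundaries of novel exons are
#' pinned by junction-spanning peptides; the merged protein must align to
#' the full-length evidence at the identity threshold and at least one
#' peptide must span a junction of the result.
#'
#' @param fragment_models list of `gene_model` named by gene id.
#' @param fragment_map one fragment map from [detect_fragment_relation()].
#' @param genome named character vector.
#' @param full_length_proteins named character vector including the map's
#'   target.
#' @param hits classified peptide hits (for novel-region clusters).
#' @param peptides character vector of all evidence peptides.
#' @param config list of thresholds (see [refine_all()]).
#' @return list with `model` and `record`, or `unresolved` (reason string).
#' @export
merge_models <- function(fragment_models, fragment_map, genome,
                         full_length_proteins, hits = list(),
                         peptides = character(), config = list()) {
  models_by_id <- stats::setNames(
    fragment_models, vapply(fragment_models, `[[`, character(1), "gene_id"))
  clusters <- .cluster_novel_hits(hits)
  unmapped <- unique(vapply(
    Filter(function(h) h$category == "unmapped", hits),
    `[[`, character(1), "peptide"))
  config$targets <- as.list(full_length_proteins)
  res <- .assemble_from_fragments(fragment_map, models_by_id, clusters,
                                  genome, unmapped, peptides, config)
  res %||% list(unresolved = "nothing to assemble", input_ids = character())
}

#' Call an intron-retention proteoform
#'
#' Requires at least one peptide placement crossing an exon/intron boundary
#' in frame. The retained segment is the maximal in-frame, stop-free
#' intronic prefix bounded by an alternative canonical GT donor and covering
#' the peptide's intronic extent; its length must be divisible by 3.
#'
#' @param model the annotated `gene_model`.
#' @param intron_hits intron-retained hits on this model's introns.
#' @param genome named character vector.
#' @return list with `pair` (canonical/retained proteins, intron index,
#'   extra residues), `retained_model` and `record`; or `NULL` when no hit
#'   crosses a junction; or `unresolved` when retention hits an in-frame
#'   stop.
#' @export
call_intron_retention <- function(model, intron_hits, genome) {
  intr <- model_introns(model)
  if (is.null(intr)) return(NULL)
  ex <- model$exons
  lens <- ex$end - ex$start + 1L
  bounds <- cumsum(lens)
  for (h in intron_hits) {
    idx <- h$intron_index
    if (is.na(idx) || idx > nrow(ex) - 1L) next
    ii <- intr[intr$index == idx, , drop = FALSE]
    if (!nrow(ii)) next
    # the hit must cross the exon/intron junction
    exon_i <- ex[idx, ]
    crosses <- .overlaps(h$blocks$start[1L], h$blocks$end[1L],
                         exon_i$start, exon_i$end) &&
      .overlaps(h$blocks$start[1L], h$blocks$end[1L], ii$start, ii$end)
    if (!crosses) next
    intron_seq <- seq_fetch(genome, ii$contig, ii$start, ii$end, ii$strand)
    cds_prefix <- spliced_cds(
      gene_model("tmp", ex[seq_len(idx), , drop = FALSE]), genome)$mrna
    # intronic extent of the hit, in coding direction
    int_extent <- if (ii$strand == "+")
      max(h$blocks$end) - ii$start + 1L else ii$end - min(h$blocks$start) + 1L
    ps <- seq(3L, nchar(intron_seq) - 4L, by = 3L)
    valid <- ps[vapply(ps, function(p) {
      substr(intron_seq, p + 1L, p + 2L) == "GT" &&
        !grepl("*", dna_translate(
          paste0(cds_prefix, substr(intron_seq, 1L, p))), fixed = TRUE)
    }, logical(1))]
    valid <- valid[valid >= int_extent]
    if (!length(valid)) {
      return(list(unresolved = sprintf(
        "intron %d retention hits an in-frame stop or lacks an alternative donor",
        idx)))
    }
    p <- max(valid)
    ret_ex <- ex
    if (ii$strand == "+") ret_ex$end[idx] <- ret_ex$end[idx] + p else
      ret_ex$start[idx] <- ret_ex$start[idx] - p
    retained_model <- gene_model(
      model$gene_id, ret_ex,
      mrna_id = paste0(model$gene_id, ".t2"),
      attrs = c(model$attrs, list(proteoform = "intron_retention")))
    canonical <- sub("\\*$", "", spliced_cds(model, genome)$protein)
    retained <- spliced_cds(retained_model, genome)$protein
    if (grepl("*", sub("\\*$", "", retained), fixed = TRUE)) {
      return(list(unresolved = "retained proteoform contains an internal stop"))
    }
    retained <- sub("\\*$", "", retained)
    pair <- list(canonical = canonical, retained = retained,
                 retained_intron_index = idx, extra_residues = p %/% 3L)
    rec <- .correction(
      "intron_retention", model$gene_id, retained_model,
      evidence = list(boundary_peptide = h$peptide),
      detail = sprintf(
        "intron %d: %d nt retained via alternative donor, %d extra residues",
        idx, p, p %/% 3L))
    return(list(pair = pair, retained_model = retained_model, record = rec))
  }
  NULL
}
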