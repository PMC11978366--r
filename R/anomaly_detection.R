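# Detection of annotation anomalies: missing/internal stop codons, missing
# starts, fragment-of-full-length relations, misclassified exons, inverted
# assembly blocks and cross-contig gaps.

.anomaly <- function(gene_ids, class, detail = "", evidence = list()) {
  stopifnot(class %in% c("missing_stop", "internal_stop", "missing_start",
                         "fragment_pair", "misclassified_exon", "inversion",
                         "cross_contig_gap", "upstream_truncation"),
            length(gene_ids) >= 1L)
  list(gene_ids = gene_ids, class = class, detail = detail,
       evidence = evidence)
}

#' Integrity checks on a single gene model
#'
#' Emits `missing_start` when the spliced CDS does not begin with ATG,
#' `internal_stop` when a stop codon occurs before the final codon and
#' `missing_stop` when the CDS does not end in TAA/TAG/TGA, in that fixed
#' order.
#'
#' @param m a `gene_model`.
#' @param genome named character vector.
#' @return list of anomaly records (possibly empty).
#' @export
check_model_integrity <- function(m, genome) {
  cds <- spliced_cds(m, genome)
  n <- nchar(cds$mrna)
  prot <- cds$protein
  out <- list()
  if (substr(cds$mrna, 1L, 3L) != "ATG") {
    out <- c(out, list(.anomaly(m$gene_id, "missing_start",
                                "spliced CDS does not begin with ATG")))
  }
  internal <- sub("\\*$", "", prot)
  if (grepl("*", internal, fixed = TRUE)) {
    out <- c(out, list(.anomaly(m$gene_id, "internal_stop",
                                sprintf("stop at residue %d of %d",
                                        regexpr("*", internal, fixed = TRUE),
                                        nchar(prot)))))
  }
  if (n < 3L || !substr(cds$mrna, n - 2L, n) %in% c("TAA", "TAG", "TGA")) {
    out <- c(out, list(.anomaly(m$gene_id, "missing_stop",
                                "spliced CDS does not end in a stop codon")))
  }
  out
}

# fixed scoring: match +2, mismatch -1, gap open -5, gap extend -1
.aa_submat <- local({
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1L]]
  m <- matrix(-1, length(aa), length(aa), dimnames = list(aa, aa))
  diag(m) <- 2
  m
})

#' Global-local protein alignment
#'
#' Aligns `query` globally against a local region of `target` with fixed
#' scoring (match +2, mismatch -1, gap open -5, gap extend -1). Identity is
#' computed over aligned columns (terminal gaps are absent by construction
#' in global-local mode).
#'
#' @param query,target non-empty protein strings.
#' @return list with `identity`, `coverage_query`, `coverage_target`,
#'   `target_span` (residue interval of `target` covered) and `score`.
#' @export
align_proteins <- function(query, target) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  al <- Biostrings::pairwiseAlignment(
    query, target, type = "global-local", substitutionMatrix = .aa_submat,
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::subject(al)), "")[[1L]]
  ncol_al <- length(pa)
  matches <- sum(pa == sa & pa != "-")
  span <- c(Biostrings::start(Biostrings::subject(al)),
            Biostrings::end(Biostrings::subject(al)))
  list(identity = matches / ncol_al,
       coverage_query = sum(pa != "-" & sa != "-") / nchar(query),
       coverage_target = (span[2L] - span[1L] + 1L) / nchar(target),
       target_span = span,
       score = Biostrings::score(al))
}

# protein of the first `keep` exons of a model, truncated at the first stop
.prefix_protein <- function(m, genome, keep) {
  mm <- m
  mm$exons <- m$exons[seq_len(keep), , drop = FALSE]
  p <- spliced_cds(mm, genome)$protein
  sub("\\*.*$", "", p)
}

#' Detect fragment-of-full-length relations
#'
#' For each full-length evidence protein, finds the set of model-encoded
#' proteins that align as compatible near-disjoint fragments, ordered along
#' the target. A model whose trailing exons spoil the alignment (a
#' misclassified intron annotated as exon) is re-tried with trailing exons
#' dropped; the dropped exons are reported so refinement can remove them.
#'
#' @param candidate_models list of `gene_model`.
#' @param full_length_proteins named character vector of evidence proteins.
#' @param genome named character vector.
#' @param thresholds list; `min_identity` (default 0.95), `min_coverage`
#'   (default 0.9, of the fragment), `overlap_tol` (default 5 residues).
#' @return list of fragment maps: each has `full_length_id`, `placements`
#'   (data.frame gene_id, span_start, span_end, kept_exons, trimmed_exons,
#'   identity), `combined_coverage`.
#' @export
detect_fragment_relation <- function(candidate_models, full_length_proteins,
                                     genome, thresholds = list()) {
  min_id <- thresholds$min_identity %||% 0.95
  min_cov <- thresholds$min_coverage %||% 0.9
  tol <- thresholds$overlap_tol %||% 5L
  maps <- list()
  prefix_cache <- new.env(parent = emptyenv())
  get_prefix <- function(mi, keep) {
    key <- paste0(mi, "|", keep)
    if (is.null(prefix_cache[[key]])) {
      prefix_cache[[key]] <- .prefix_protein(candidate_models[[mi]], genome,
                                             keep)
    }
    prefix_cache[[key]]
  }
  for (tid in names(full_length_proteins)) {
    target <- sub("\\*$", "", full_length_proteins[[tid]])
    pl <- NULL
    for (mi in seq_along(candidate_models)) {
      m <- candidate_models[[mi]]
      n_ex <- nrow(m$exons)
      for (keep in rev(seq_len(n_ex))) {
        prot <- get_prefix(mi, keep)
        if (nchar(prot) < 8L) next
        al <- align_proteins(prot, target)
        if (al$identity >= min_id && al$coverage_query >= min_cov) {
          pl <- rbind(pl, data.frame(
            gene_id = m$gene_id, span_start = al$target_span[1L],
            span_end = al$target_span[2L], kept_exons = keep,
            trimmed_exons = n_ex - keep, identity = al$identity))
          break
        }
      }
    }
    if (is.null(pl)) next
    pl <- pl[order(pl$span_start, pl$span_end), , drop = FALSE]
    # near-disjoint check: consecutive placements may overlap by <= tol
    if (nrow(pl) > 1L) {
      ok <- pl$span_start[-1L] >= pl$span_end[-nrow(pl)] - tol
      keep_rows <- c(TRUE, ok)
      pl <- pl[keep_rows, , drop = FALSE]
    }
    covered <- sum(pl$span_end - pl$span_start + 1L)
    maps[[length(maps) + 1L]] <- list(
      full_length_id = tid, placements = pl,
      combined_coverage = min(1, covered / nchar(target)))
  }
  maps
}

# maximal exact prefix length of the mRNA suffix starting at q occurring in
# either orientation of the contig (`fwd`/`rcv` are plain character
# strings); returns NULL or list(len, start, end, strand) in genomic
# coordinates
.max_prefix_match <- function(mrna, q, fwd, rcv, L, min_block, prev_end) {
  rem <- nchar(mrna) - q + 1L
  best <- NULL
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") fwd else rcv
    lo <- min_block; hi <- rem
    if (lo > rem) next
    if (!grepl(substr(mrna, q, q + lo - 1L), subj, fixed = TRUE)) next
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      hit <- grepl(substr(mrna, q, q + mid - 1L), subj, fixed = TRUE)
      if (hit) lo <- mid else hi <- mid - 1L
    }
    starts <- as.integer(gregexpr(substr(mrna, q, q + lo - 1L), subj,
                                  fixed = TRUE)[[1L]])
    # prefer the leftmost occurrence colinear with the previous same-strand
    # anchor (coordinates are strand-local: plus space or revcomp space)
    anchor <- if (strand == "+") prev_end$plus else prev_end$minus
    pick <- starts[starts > anchor]
    s_local <- if (length(pick)) pick[1L] else starts[1L]
    e_local <- s_local + lo - 1L
    if (strand == "+") {
      gs <- s_local; ge <- e_local
    } else {
      gs <- L - e_local + 1L; ge <- L - s_local + 1L
    }
    cand <- list(len = lo, start = gs, end = ge, strand = strand,
                 local_end = e_local)
    if (is.null(best) || cand$len > best$len) best <- cand
  }
  best
}

#' Spliced alignment of a transcript onto a contig
#'
#' Greedy maximal-exact-match chaining of mRNA blocks onto the contig, both
#' strands, non-overlapping in the mRNA. Returns the ordered genomic block
#' chain (the inferred exons, in transcription order) and any mRNA segments
#' that could not be placed — evidence of an assembly gap on another contig.
#'
#' @param mrna transcript sequence (coding strand).
#' @param contig_seq contig sequence.
#' @param contig_name name recorded in the chain.
#' @param min_block minimum exact block length in nt (default 20).
#' @return list with `blocks` (data.frame mrna_start, mrna_end, contig,
#'   start, end, strand) and `unplaced` (data.frame mrna_start, mrna_end).
#' @export
spliced_align_transcript <- function(mrna, contig_seq,
                                     contig_name = "contig",
                                     min_block = 20L) {
  fwd <- contig_seq
  rcv <- revcomp(contig_seq)
  L <- nchar(contig_seq)
  n <- nchar(mrna)
  blocks <- NULL
  unplaced <- NULL
  q <- 1L
  prev_end <- list(plus = 0L, minus = 0L)
  gap_start <- NA_integer_
  while (q + min_block - 1L <= n) {
    hit <- .max_prefix_match(mrna, q, fwd, rcv, L, min_block, prev_end)
    if (is.null(hit)) {
      if (is.na(gap_start)) gap_start <- q
      q <- q + 1L
      next
    }
    if (!is.na(gap_start)) {
      unplaced <- rbind(unplaced, data.frame(mrna_start = gap_start,
                                             mrna_end = q - 1L))
      gap_start <- NA_integer_
    }
    blocks <- rbind(blocks, data.frame(
      mrna_start = q, mrna_end = q + hit$len - 1L, contig = contig_name,
      start = hit$start, end = hit$end, strand = hit$strand))
    if (hit$strand == "+") prev_end$plus <- hit$local_end else
      prev_end$minus <- hit$local_end
    q <- q + hit$len
  }
  if (q <= n) {
    unplaced <- rbind(unplaced, data.frame(
      mrna_start = if (is.na(gap_start)) q else gap_start, mrna_end = n))
  }
  list(blocks = blocks, unplaced = unplaced)
}

#' Detect an inverted assembly block from a transcript chain
#'
#' A chain whose blocks map on both strands of one contig indicates that a
#' genomic block was assembled in inverted orientation: the minority-strand
#' blocks delimit the inverted interval and the models annotated inside it
#' carry the wrong strand.
#'
#' @param chain result of [spliced_align_transcript()].
#' @param models list of `gene_model` (used to name affected models).
#' @param contig_name contig the chain was built on.
#' @return list of anomaly records of class `inversion` (empty if the chain
#'   is strand-consistent); each carries `interval` in its evidence.
#' @export
detect_inversion <- function(chain, models, contig_name = "contig") {
  b <- chain$blocks
  if (is.null(b) || length(unique(b$strand)) < 2L) return(list())
  tab <- table(b$strand)
  minority <- names(tab)[which.min(tab)]
  mb <- b[b$strand == minority, , drop = FALSE]
  interval <- c(min(mb$start), max(mb$end))
  affected <- vapply(models, function(m) {
    m$contig == contig_name &&
      any(.overlaps(m$exons$start, m$exons$end, interval[1L], interval[2L]))
  }, logical(1))
  ids <- vapply(models[affected], function(m) m$gene_id, character(1))
  if (!length(ids)) ids <- NA_character_
  list(.anomaly(ids, "inversion",
                sprintf("inverted block %s:%d-%d (minority strand %s)",
                        contig_name, interval[1L], interval[2L], minority),
                evidence = list(interval = interval, chain = chain,
                                contig = contig_name,
                                minority_strand = minority)))
}

#' Anomaly list as a data.frame
#' @param anomalies list of anomaly records.
#' @return data.frame with `gene_ids` (comma-joined), `class`, `detail`,
#'   `n_evidence`.
#' @export
anomaly_table <- function(anomalies) {
  if (!length(anomalies)) {
    return(data.frame(gene_ids = character(), class = character(),
                      detail = character(), n_evidence = integer()))
  }
  do.call(rbind, lapply(anomalies, function(a) data.frame(
    gene_ids = paste(a$gene_ids, collapse = ","), class = a$class,
    detail = a$detail, n_evidence = length(a$evidence))))
}
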