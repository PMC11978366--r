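#' Gene model container
#'
#' A gene model is an ordered exon chain in 5'->3' transcription order. Exons
#' normally share one contig and strand; a model repaired across an assembly
#' gap may carry exons on a second contig (a "cross-contig patch"), which is
#' why each exon row records its own contig and strand. Coordinates are
#' 1-based inclusive throughout.
#'
#' @param gene_id gene identifier.
#' @param exons data.frame with columns `contig`, `start`, `end`, `strand`,
#'   rows in transcription order (5' exon first).
#' @param mrna_id transcript identifier; defaults to `<gene_id>.t1`.
#' @param attrs named list of free-form attributes (provenance such as
#'   `merged_from`, `status`, `part`).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, exons, mrna_id = paste0(gene_id, ".t1"),
                       attrs = list()) {
  stopifnot(is.data.frame(exons),
            all(c("contig", "start", "end", "strand") %in% names(exons)),
            nrow(exons) >= 1L)
  exons <- exons[, c("contig", "start", "end", "strand")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  if (any(exons$start < 1L) || any(exons$start > exons$end)) {
    stop("gene_model '", gene_id, "': invalid exon interval")
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("gene_model '", gene_id, "': strand must be + or -")
  }
  m <- structure(list(gene_id = gene_id, mrna_id = mrna_id,
                      contig = exons$contig[1L], strand = exons$strand[1L],
                      exons = exons, attrs = attrs),
                 class = "gene_model")
  validate_gene_model(m)
  m
}

#' Validate a gene model's structural invariants
#'
#' Checks per-contig exon non-overlap and that the transcription order of the
#' exon list is consistent with the strand (ascending coordinates on `+`,
#' descending on `-`). Cross-contig models are checked contig by contig.
#'
#' @param m a `gene_model`.
#' @return `m`, invisibly; stops on violation.
#' @export
validate_gene_model <- function(m) {
  ex <- m$exons
  for (ctg in unique(ex$contig)) {
    e <- ex[ex$contig == ctg, , drop = FALSE]
    if (.any_overlap(e$start, e$end)) {
      stop("gene_model '", m$gene_id, "': overlapping exons on ", ctg)
    }
    if (length(unique(e$strand)) > 1L) {
      stop("gene_model '", m$gene_id, "': mixed strands on ", ctg)
    }
    if (nrow(e) > 1L) {
      ord_ok <- if (e$strand[1L] == "+") all(diff(e$start) > 0) else
        all(diff(e$start) < 0)
      if (!ord_ok) {
        stop("gene_model '", m$gene_id,
             "': exon order inconsistent with strand on ", ctg)
      }
    }
  }
  invisible(m)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%s %d exon(s), %d nt CDS\n",
              x$gene_id, x$mrna_id, x$contig, x$strand, nrow(x$exons),
              sum(x$exons$end - x$exons$start + 1L)))
  invisible(x)
}

#' Is the model patched across more than one contig?
#' @param m a `gene_model`.
#' @return logical scalar.
#' @export
is_cross_contig <- function(m) length(unique(m$exons$contig)) > 1L

#' Total spliced CDS length in nucleotides
#' @param m a `gene_model`.
#' @return integer scalar.
#' @export
cds_length <- function(m) sum(m$exons$end - m$exons$start + 1L)

#' Genomic span of a model on its primary contig
#' @param m a `gene_model`.
#' @return integer vector `c(start, end)` on `m$contig`.
#' @export
model_span <- function(m) {
  e <- m$exons[m$exons$contig == m$contig, , drop = FALSE]
  c(min(e$start), max(e$end))
}

#' Start/stop completeness flags for a model
#'
#' @param m a `gene_model`.
#' @param genome named character vector of contigs.
#' @return list with `has_start` (CDS begins ATG) and `has_stop` (CDS ends in
#'   TAA/TAG/TGA).
#' @export
model_flags <- function(m, genome) {
  cds <- spliced_cds(m, genome)$mrna
  n <- nchar(cds)
  list(has_start = substr(cds, 1L, 3L) == "ATG",
       has_stop = n >= 3L && substr(cds, n - 2L, n) %in% c("TAA", "TAG", "TGA"))
}

# introns of a model restricted to one contig, in transcription order:
# data.frame(contig, start, end, strand, index)
model_introns <- function(m) {
  ex <- m$exons
  out <- NULL
  for (i in seq_len(nrow(ex) - 1L)) {
    if (ex$contig[i] != ex$contig[i + 1L]) next  # assembly gap, not an intron
    if (ex$strand[i] == "+") {
      s <- ex$end[i] + 1L; e <- ex$start[i + 1L] - 1L
    } else {
      s <- ex$end[i + 1L] + 1L; e <- ex$start[i] - 1L
    }
    if (s > e) next
    out <- rbind(out, data.frame(contig = ex$contig[i], start = s, end = e,
                                 strand = ex$strand[i], index = i))
  }
  out
}
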