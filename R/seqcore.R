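# Deterministic sequence primitives: translation, spliced CDS assembly,
# tryptic digestion, six-frame ORF scanning, canonical splice-site discovery.

#' Translate DNA in a given frame
#'
#' Standard genetic code. Translation runs to the end of the sequence; a
#' trailing partial codon is dropped. Stop codons are rendered `*` and codons
#' containing `N` are rendered `X`.
#'
#' @param dna character scalar over ACGTN.
#' @param offset reading-frame offset, 0, 1 or 2.
#' @return protein string (possibly empty).
#' @export
dna_translate <- function(dna, offset = 0L) {
  stopifnot(offset %in% 0:2)
  s <- substr(dna, offset + 1L, nchar(dna))
  n <- (nchar(s) %/% 3L) * 3L
  if (n == 0L) return("")
  cods <- substring(s, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa <- .CODON_AA[cods]
  aa[is.na(aa)] <- "X"   # codons containing N (or other ambiguity)
  paste(aa, collapse = "")
}

# standard genetic code, keyed by codon (insect nuclear genes; no
# alternative codes)
.CODON_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
})

#' Assemble the spliced CDS and protein of a gene model
#'
#' Exon sequences are fetched in transcription order (reverse-complemented for
#' minus-strand exons) and concatenated; the protein is the frame-0
#' translation of the result.
#'
#' @param m a `gene_model`.
#' @param genome named character vector of contig sequences.
#' @return list with `mrna` (spliced CDS, coding strand) and `protein`.
#' @export
spliced_cds <- function(m, genome) {
  ex <- m$exons
  parts <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    parts[i] <- seq_fetch(genome, ex$contig[i], ex$start[i], ex$end[i],
                          ex$strand[i])
  }
  mrna <- paste(parts, collapse = "")
  list(mrna = mrna, protein = dna_translate(mrna, 0L))
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, emitting
#' all products with up to `missed_cleavages` internal uncleaved sites,
#' filtered to `[min_len, max_len]`.
#'
#' @param protein protein string without `*`.
#' @param missed_cleavages maximum internal missed cleavage sites.
#' @param min_len,max_len peptide length filter (residues).
#' @return character vector of peptides, ordered by start position then span.
#' @export
tryptic_digest <- function(protein, missed_cleavages = 2L, min_len = 7L,
                           max_len = 35L) {
  tryptic_digest_pos(protein, missed_cleavages, min_len, max_len)$peptide
}

#' Tryptic digestion with residue coordinates
#'
#' Same cleavage rule as [tryptic_digest()] but returns the residue interval
#' and missed-cleavage count of each product, which the synthetic-data
#' generator and the peptide-mapping tests need.
#'
#' @inheritParams tryptic_digest
#' @return data.frame with columns `peptide`, `start`, `end` (1-based residue
#'   interval in `protein`) and `mc`.
#' @export
tryptic_digest_pos <- function(protein, missed_cleavages = 2L, min_len = 7L,
                               max_len = 35L) {
  n <- nchar(protein)
  empty <- data.frame(peptide = character(), start = integer(),
                      end = integer(), mc = integer())
  if (n == 0L) return(empty)
  if (grepl("\\*", protein)) stop("protein contains a stop symbol '*'")
  res <- strsplit(protein, "")[[1L]]
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)            # base peptide i = (bounds[i]+1)..bounds[i+1]
  nb <- length(bounds) - 1L
  out <- empty
  for (i in seq_len(nb)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > nb) break
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      out <- rbind(out, data.frame(peptide = substr(protein, s, e),
                                   start = s, end = e, mc = mc))
    }
  }
  if (nrow(out)) out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Six-frame ORF scan of a contig
#'
#' Finds every maximal stop-free translated stretch of at least
#' `min_protein_len` residues in all six reading frames, with its exact
#' genomic projection (1-based inclusive, on the given contig).
#'
#' @param contig_seq contig sequence (ACGTN).
#' @param min_protein_len minimum stretch length in residues.
#' @param contig_name name recorded in the output.
#' @return data.frame with columns `contig`, `strand`, `frame`, `start`,
#'   `end`, `protein`.
#' @export
six_frame_scan <- function(contig_seq, min_protein_len = 8L,
                           contig_name = "contig") {
  L <- nchar(contig_seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig_seq else revcomp(contig_seq)
    for (frame in 0:2) {
      prot <- dna_translate(s, frame)
      if (nchar(prot) == 0L) next
      # maximal stop-free stretches
      pieces <- gregexpr("[^*]+", prot)[[1L]]
      if (pieces[1L] == -1L) next
      lens <- attr(pieces, "match.length")
      for (k in seq_along(pieces)) {
        if (lens[k] < min_protein_len) next
        a <- pieces[k]; b <- pieces[k] + lens[k] - 1L
        nt_s <- frame + 3L * (a - 1L) + 1L   # on strand-local coordinates
        nt_e <- frame + 3L * b
        if (strand == "+") {
          gs <- nt_s; ge <- nt_e
        } else {
          gs <- L - nt_e + 1L; ge <- L - nt_s + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          contig = contig_name, strand = strand, frame = frame,
          start = gs, end = ge, protein = substr(prot, a, b))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      protein = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$strand, res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Canonical splice-site discovery
#'
#' Reports every canonical donor (GT) and acceptor (AG) dinucleotide on both
#' strands within a window, in coding-strand orientation. The reported
#' `position` is the first intronic base for a donor and the last intronic
#' base for an acceptor, in genomic (plus-strand) coordinates.
#'
#' @param contig_seq contig sequence.
#' @param start,end 1-based inclusive search window (defaults to the whole
#'   contig).
#' @return data.frame with columns `strand`, `kind`, `position`.
#' @export
find_splice_sites <- function(contig_seq, start = 1L, end = nchar(contig_seq)) {
  win <- substr(contig_seq, start, end)
  hit_pos <- function(pat) {
    # two-letter patterns with distinct letters cannot self-overlap, so plain
    # gregexpr enumerates every occurrence
    g <- gregexpr(pat, win, fixed = TRUE)[[1L]]
    if (g[1L] == -1L) integer() else as.integer(g) + start - 1L
  }
  mk <- function(strand, kind, pos) {
    if (!length(pos)) return(NULL)
    data.frame(strand = strand, kind = kind, position = pos)
  }
  out <- rbind(
    mk("+", "donor", hit_pos("GT")),
    mk("+", "acceptor", hit_pos("AG") + 1L),
    mk("-", "donor", hit_pos("AC") + 1L),
    mk("-", "acceptor", hit_pos("CT"))
  )
  if (is.null(out)) {
    return(data.frame(strand = character(), kind = character(),
                      position = integer()))
  }
  out <- out[order(out$position, out$strand, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}
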