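# Small shared helpers: sequence fetching, reverse complement, interval utils.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' @param x character scalar over the ACGTN alphabet.
#' @return character scalar, reverse complement of `x`.
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Fetch a genomic interval
#'
#' Coordinates are 1-based inclusive. For `strand == "-"` the reverse
#' complement is returned, i.e. the coding-strand reading of the interval.
#'
#' @param genome named character vector of contig sequences.
#' @param contig contig name.
#' @param start,end 1-based inclusive interval.
#' @param strand `"+"` or `"-"`.
#' @return character scalar.
#' @export
seq_fetch <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) {
    stop("unknown contig: ", contig)
  }
  len <- nchar(genome[[contig]])
  if (start < 1L || end > len || start > end) {
    stop(sprintf("interval %d-%d out of bounds for contig %s (length %d)",
                 start, end, contig, len))
  }
  s <- substr(genome[[contig]], start, end)
  if (identical(strand, "-")) revcomp(s) else s
}

# intervals: data.frame(start, end); TRUE if any pair overlaps
.any_overlap <- function(start, end) {
  if (length(start) < 2L) return(FALSE)
  o <- order(start)
  s <- start[o]; e <- end[o]
  any(s[-1L] <= e[-length(e)])
}

# do [a1,b1] and [a2,b2] overlap?
.overlaps <- function(a1, b1, a2, b2) a1 <= b2 & a2 <= b1

.is_dna <- function(x) grepl("^[ACGTN]+$", x)

.AA20 <- "ACDEFGHIKLMNPQRSTVWY"
.is_protein <- function(x) grepl(sprintf("^[%sX*]+$", .AA20), x)

# Fold I/L for mass-spec-equivalent matching
.il_fold <- function(x) chartr("I", "L", x)
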