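# Independent oracle implementations used to cross-check the package's
# sequence primitives. They deliberately take different routes from the
# implementation: Biostrings S4 translation instead of the package's codon
# lookup, position-by-position scans instead of regex/ORF chaining, and a
# plain dynamic-programming aligner instead of Biostrings::pairwiseAlignment.

oracle_translate <- function(dna, offset = 0) {
  s <- substr(dna, offset + 1, nchar(dna))
  n <- (nchar(s) %/% 3) * 3
  if (n == 0) return("")
  s <- substr(s, 1, n)
  if (!grepl("N", s, fixed = TRUE)) {
    return(suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(s),
                            no.init.codon = TRUE))))
  }
  out <- character(n / 3)
  for (i in seq_len(n / 3)) {
    codon <- substr(s, 3 * i - 2, 3 * i)
    out[i] <- if (grepl("N", codon)) "X" else
      as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                         no.init.codon = TRUE))
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# brute-force six-frame stop-free stretches with genomic projection
oracle_six_frame <- function(contig_seq, min_len, contig_name = "contig") {
  L <- nchar(contig_seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig_seq else oracle_revcomp(contig_seq)
    for (frame in 0:2) {
      prot <- oracle_translate(s, frame)
      if (nchar(prot) == 0) next
      aa <- strsplit(prot, "")[[1]]
      i <- 1
      while (i <= length(aa)) {
        if (aa[i] == "*") { i <- i + 1; next }
        j <- i
        while (j < length(aa) && aa[j + 1] != "*") j <- j + 1
        if (j - i + 1 >= min_len) {
          nt_s <- frame + 3 * (i - 1) + 1
          nt_e <- frame + 3 * j
          gs <- if (strand == "+") nt_s else L - nt_e + 1
          ge <- if (strand == "+") nt_e else L - nt_s + 1
          rows[[length(rows) + 1]] <- data.frame(
            contig = contig_name, strand = strand, frame = frame,
            start = gs, end = ge,
            protein = paste(aa[i:j], collapse = ""))
        }
        i <- j + 1
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      protein = character()))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$strand, res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# brute-force contiguous genomic placements of a peptide: every residue
# offset of every frame on both strands is compared directly
oracle_peptide_placements <- function(peptide, contig_seq) {
  L <- nchar(contig_seq)
  plen <- nchar(peptide)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig_seq else oracle_revcomp(contig_seq)
    for (frame in 0:2) {
      prot <- oracle_translate(s, frame)
      np <- nchar(prot)
      if (np < plen) next
      for (i in seq_len(np - plen + 1)) {
        if (substr(prot, i, i + plen - 1) == peptide) {
          nt_s <- frame + 3 * (i - 1) + 1
          nt_e <- frame + 3 * (i + plen - 1)
          gs <- if (strand == "+") nt_s else L - nt_e + 1
          ge <- if (strand == "+") nt_e else L - nt_s + 1
          rows[[length(rows) + 1]] <- data.frame(start = gs, end = ge,
                                                 strand = strand)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  do.call(rbind, rows)
}

# full affine-gap dynamic programming, query-global / target-local, same
# scoring as the package aligner (match +2, mismatch -1, open -5, extend -1);
# returns the optimal score
oracle_glocal_score <- function(query, target,
                                match = 2, mismatch = -1,
                                open = -5, extend = -1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ending in substitution
  X <- matrix(NEG, n + 1, m + 1)  # ending in gap-in-target
  Y <- matrix(NEG, n + 1, m + 1)  # ending in gap-in-query
  M[1, ] <- 0                     # local in target: free start anywhere
  for (i in 2:(n + 1)) {
    X[i, 1] <- max(M[i - 1, 1] + open + extend, X[i - 1, 1] + extend)
    sub_row <- ifelse(q[i - 1] == t, match, mismatch)
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        sub_row[j - 1]
      X[i, j] <- max(M[i - 1, j] + open + extend, X[i - 1, j] + extend)
      Y[i, j] <- max(M[i, j - 1] + open + extend, Y[i, j - 1] + extend)
    }
  }
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ])  # free end anywhere in target
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
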