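# External representations: FASTA, GFF3, peptide TSV, BED, report JSON.
# Convention: GFF3/FASTA/internal coordinates are 1-based inclusive; BED
# output is 0-based half-open per the BED standard.

#' Parse a FASTA file
#'
#' Light line-level validation (so malformed input is reported with a line
#' number) followed by Biostrings parsing. Sequences are uppercased.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `description`, `sequence`, one row
#'   per record, in file order.
#' @export
parse_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L]) {
    stop("FASTA parse error at line 1: expected '>' header")
  }
  if (any(bad <- hdr & nchar(sub("^>", "", lines)) == 0L)) {
    stop("FASTA parse error at line ", which(bad)[1L], ": empty header")
  }
  run <- cumsum(hdr)
  seq_chars <- tapply(nchar(lines[!hdr]), run[!hdr], sum)
  n_rec <- sum(hdr)
  empty <- setdiff(seq_len(n_rec), as.integer(names(seq_chars)[seq_chars > 0]))
  if (length(empty)) {
    stop("FASTA parse error at line ", which(hdr)[empty[1L]],
         ": empty sequence for record '",
         sub("^>", "", lines[which(hdr)[empty[1L]]]), "'")
  }
  set <- Biostrings::readBStringSet(path)
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  data.frame(id = id, description = desc,
             sequence = toupper(as.character(set)), row.names = NULL)
}

#' Write records to FASTA
#'
#' @param records data.frame as returned by [parse_fasta()], or a named
#'   character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records))
  }
  nm <- ifelse(nchar(records$description) > 0,
               paste(records$id, records$description), records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Collapse FASTA records into a named sequence vector
#' @param records data.frame from [parse_fasta()].
#' @return named character vector keyed by record id.
#' @export
as_genome <- function(records) stats::setNames(records$sequence, records$id)

.gff_escape <- function(x) gsub(",", "%2C", gsub(";", "%3B", x))

#' Parse gene models from GFF3
#'
#' Accepts a gene/mRNA/exon or gene/mRNA/CDS hierarchy (CDS wins when both
#' feature types are present under one mRNA). One `gene_model` is returned
#' per mRNA; minus-strand exon lists are ordered 5'->3'. mRNA features split
#' into `part=` pieces (the cross-contig convention used by [write_gff3()])
#' are reassembled into a single model.
#'
#' @param path GFF3 file.
#' @param mixed_strand `"error"` (default) to fail on an mRNA whose coding
#'   features disagree in strand, `"warn"` to keep the model and record the
#'   conflict in `attrs$mixed_strand` — strand disagreement is itself evidence
#'   of an inverted-assembly anomaly.
#' @return list of `gene_model` objects.
#' @export
parse_gff3 <- function(path, mixed_strand = c("error", "warn")) {
  mixed_strand <- match.arg(mixed_strand)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) return(list())
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) as.character(v[1L]) else NA_character_, character(1))
  df$parent1 <- if ("Parent" %in% names(df)) first_parent(df$Parent) else NA

  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  kids <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(kids) && anyNA(kids$parent1)) {
    stop("GFF3 parse error: exon/CDS feature without Parent")
  }
  orphans <- setdiff(kids$parent1, mrna$ID)
  if (length(orphans)) {
    stop("GFF3 parse error: exon/CDS parent not an mRNA: ",
         paste(orphans, collapse = ", "))
  }

  std <- c("seqnames", "start", "end", "width", "strand", "source", "type",
           "score", "phase", "ID", "Parent", "parent1", "Name", "part")
  models <- list()
  # group mRNA rows: part-split mRNAs share "<mrna_id>.p<k>" IDs and a part attr
  has_part <- if ("part" %in% names(mrna)) !is.na(mrna$part) else
    rep(FALSE, nrow(mrna))
  mrna$base_id <- ifelse(has_part, sub("\\.p[0-9]+$", "", mrna$ID), mrna$ID)
  for (bid in unique(mrna$base_id)) {
    rows <- mrna[mrna$base_id == bid, , drop = FALSE]
    if (nrow(rows) > 1L) rows <- rows[order(as.integer(rows$part)), , drop = FALSE]
    gene_id <- rows$parent1[1L]
    if (is.na(gene_id)) gene_id <- bid
    ex_all <- NULL
    for (ri in seq_len(nrow(rows))) {
      ch <- kids[kids$parent1 == rows$ID[ri], , drop = FALSE]
      if (!nrow(ch)) next
      if (any(ch$type == "CDS")) ch <- ch[ch$type == "CDS", , drop = FALSE]
      if (length(unique(ch$strand)) > 1L) {
        msg <- paste0("mRNA ", rows$ID[ri], " has mixed-strand features: ",
                      paste(unique(ch$strand), collapse = "/"))
        if (mixed_strand == "error") stop("GFF3 parse error: ", msg)
        warning(msg)
        ch$strand <- ch$strand[1L]
      }
      ch <- if (ch$strand[1L] == "+") ch[order(ch$start), , drop = FALSE] else
        ch[order(-ch$start), , drop = FALSE]
      ex_all <- rbind(ex_all, data.frame(contig = ch$seqnames, start = ch$start,
                                         end = ch$end, strand = ch$strand))
    }
    if (is.null(ex_all)) next
    extra <- rows[1L, setdiff(names(rows), c(std, "base_id")), drop = FALSE]
    attrs <- as.list(extra[, !vapply(extra, function(v) is.na(v)[1L],
                                     logical(1)), drop = FALSE])
    attrs <- lapply(attrs, as.character)
    models[[length(models) + 1L]] <- gene_model(
      gene_id = gene_id, exons = ex_all, mrna_id = bid, attrs = attrs)
  }
  models
}

#' Write gene models to GFF3
#'
#' Emits a gene / mRNA / CDS hierarchy with computed phase. A cross-contig
#' model is serialized as one mRNA per contig sharing the gene ID, with
#' `part=` attributes in transcription order. Provenance attributes in
#' `m$attrs` (e.g. `merged_from`, `status`) are written on the mRNA line.
#'
#' @param models list of `gene_model` objects.
#' @param path output file.
#' @return `path`, invisibly. `parse_gff3(write_gff3(m))` reproduces `m`.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  fmt <- function(contig, type, start, end, strand, phase, attrs) {
    sprintf("%s\tproteorefine\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            contig, type, start, end, strand, phase, attrs)
  }
  for (m in models) {
    ex <- m$exons
    parts <- split(seq_len(nrow(ex)), cumsum(c(TRUE, diff(match(
      ex$contig, unique(ex$contig))) != 0)))
    multi <- length(parts) > 1L
    extra <- ""
    if (length(m$attrs)) {
      extra <- paste0(";", paste0(names(m$attrs), "=",
                                  .gff_escape(unlist(m$attrs)),
                                  collapse = ";"))
    }
    cum <- 0L
    for (pi in seq_along(parts)) {
      idx <- parts[[pi]]
      e <- ex[idx, , drop = FALSE]
      ctg <- e$contig[1L]
      span <- c(min(e$start), max(e$end))
      mrna_id <- if (multi) sprintf("%s.p%d", m$mrna_id, pi) else m$mrna_id
      part_attr <- if (multi) sprintf(";part=%d", pi) else ""
      lines <- c(lines,
                 fmt(ctg, "gene", span[1L], span[2L], e$strand[1L], ".",
                     sprintf("ID=%s", m$gene_id)),
                 fmt(ctg, "mRNA", span[1L], span[2L], e$strand[1L], ".",
                     sprintf("ID=%s;Parent=%s%s%s", mrna_id, m$gene_id,
                             part_attr, extra)))
      for (k in seq_len(nrow(e))) {
        phase <- (3L - cum %% 3L) %% 3L
        lines <- c(lines, fmt(e$contig[k], "CDS", e$start[k], e$end[k],
                              e$strand[k], as.character(phase),
                              sprintf("ID=%s.cds%d;Parent=%s", mrna_id, k,
                                      mrna_id)))
        cum <- cum + e$end[k] - e$start[k] + 1L
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse an MS peptide table
#'
#' TSV with header columns `peptide`, `psm_count`, `source`. Duplicate
#' peptide sequences are aggregated by summing `psm_count`; sources are
#' joined. Aggregated counts therefore equal the column sum of the input.
#'
#' @param path TSV file.
#' @return data.frame with columns `peptide`, `psm_count`, `source`.
#' @export
parse_peptides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "psm_count", "source")
  if (!all(need %in% names(df))) {
    stop("peptide table must have columns: ", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    p <- df$peptide[i]
    bad <- regmatches(p, regexpr(sprintf("[^%s]", .AA20), p))
    if (length(bad) && nchar(bad)) {
      stop(sprintf("peptide table row %d: invalid residue '%s' in '%s'",
                   i, bad, p))
    }
    if (nchar(p) < 5L) {
      stop(sprintf("peptide table row %d: peptide shorter than 5 residues", i))
    }
    if (df$psm_count[i] < 0) {
      stop(sprintf("peptide table row %d: negative psm_count", i))
    }
  }
  agg <- stats::aggregate(psm_count ~ peptide, data = df, FUN = sum)
  src <- vapply(agg$peptide, function(p)
    paste(sort(unique(df$source[df$peptide == p])), collapse = ","),
    character(1))
  out <- data.frame(peptide = agg$peptide, psm_count = agg$psm_count,
                    source = unname(src))
  out[order(out$peptide), , drop = FALSE]
}

#' Write a peptide table
#' @param peptides data.frame with `peptide`, `psm_count`, `source`.
#' @param path output TSV.
#' @export
write_peptides <- function(peptides, path) {
  utils::write.table(peptides[, c("peptide", "psm_count", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export peptide-to-genome hits as extended BED
#'
#' BED6 plus a seventh `category` column; one row per coding block (a
#' junction-spanning peptide contributes one row per block). BED rows are
#' 0-based half-open.
#'
#' @param hits hit list from [classify_all()].
#' @param path output BED file.
#' @export
write_hits_bed <- function(hits, path) {
  rows <- character()
  for (h in hits) {
    if (h$category == "unmapped") next
    for (k in seq_len(nrow(h$blocks))) {
      rows <- c(rows, sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s",
                              h$contig, h$blocks$start[k] - 1L,
                              h$blocks$end[k], h$peptide,
                              h$psm_count, h$strand, h$category))
    }
  }
  writeLines(rows, path)
  invisible(path)
}
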