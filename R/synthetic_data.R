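# Synthetic scenario bundles: toy genomes with known-true gene models,
# annotations corrupted with each documented anomaly class, and evidence
# (tryptic peptides, transcripts, full-length proteins) sufficient to drive
# every refinement stage.
#
# Scenario classes
#   A  gene split in two + hidden intergenic exon + wrong-strand fragment
#   B  terminal exon fragment stranded on another contig (assembly break)
#   C  missing terminal exon + intronic sequence misannotated as an exon
#   D  three-way split of a gene that natively spans two contigs
#   E  adjacent fragments + unannotated internal exon + C-terminal exon on
#      another contig
#   F  inverted genomic block with a wrong-strand model inside it
#   G  two missing upstream exons
#   H  intron-retention proteoform (annotation itself is correct)

.SCENARIO_CLASSES <- c("A", "B", "C", "D", "E", "F", "G", "H")

.EXPECTED_CORRECTION <- c(
  A = "merge", B = "cross_contig_patch", C = "terminal_exon_addition",
  D = "merge", E = "merge", F = "inversion_fix",
  G = "upstream_exon_addition", H = "intron_retention")

# residue alphabet for generated proteins: no K/R (inserted deliberately to
# control tryptic sites) and no P (keeps the cleavage rule simple; the
# KP exception is exercised by unit tests on literal strings)
.CORE_AA <- strsplit("ACDEFGHILMNQSTVWY", "")[[1L]]

.REV_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rev_translate <- function(protein) {
  res <- strsplit(protein, "")[[1L]]
  paste(vapply(res, function(a) {
    cods <- .REV_CODON[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# protein of length len: starts M, K/R inserted every 8-14 residues, none in
# the last `tail_free` residues
.rand_protein <- function(len, tail_free = 2L) {
  res <- c("M", sample(.CORE_AA, len - 1L, replace = TRUE))
  pos <- 1L
  repeat {
    pos <- pos + sample(8:14, 1L)
    if (pos > len - tail_free) break
    res[pos] <- sample(c("K", "R"), 1L)
  }
  paste(res, collapse = "")
}

# does some tryptic peptide (<= mc missed cleavages) bridge CDS position
# `c` with at least `margin` nt on each side?
.bridging_rows <- function(digest, c, margin = 6L) {
  nt_s <- 3L * (digest$start - 1L) + 1L
  nt_e <- 3L * digest$end
  digest[nt_s <= c - margin + 1L & nt_e >= c + margin, , drop = FALSE]
}

# is there an mc=0 peptide wholly inside residue interval [a, b]?
.interior_rows <- function(digest, a, b) {
  digest[digest$mc == 0L & digest$start >= a & digest$end <= b, ,
         drop = FALSE]
}

#' Generate a random multi-exon gene with ground truth
#'
#' Builds a random coding gene: CDS begins ATG, ends with a stop codon,
#' contains no internal stop (guaranteed by sampling real codons, not by
#' post-hoc editing); introns begin GT and end AG. Deterministic given the
#' seed. Exon junctions listed in `phase0_junctions` fall on codon
#' boundaries; no exon after the first begins with G (keeps exact-match
#' transcript chaining free of boundary micro-homology); every junction is
#' crossed by at least one tryptic peptide usable as bridging evidence.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param n_exons number of exons (>= 1).
#' @param exon_len_range,intron_len_range length ranges in nt.
#' @param gene_id,contig_name identifiers for the truth model.
#' @param phase0_junctions junction indices (junction j separates exon j and
#'   j+1) forced onto codon boundaries.
#' @param flank intergenic padding on each side, nt.
#' @return list with `seq` (contig sequence), `model` (truth `gene_model`,
#'   plus strand), `protein` (no stop symbol), `cds`, `junction_nt`
#'   (cumulative CDS nt position at each junction), `introns`, `digest`
#'   (tryptic peptide table of the protein, mc <= 2, length 7-35).
#' @export
generate_gene <- function(seed = NULL, n_exons = 5L,
                          exon_len_range = c(90L, 180L),
                          intron_len_range = c(90L, 250L),
                          gene_id = "gene1", contig_name = "contig1",
                          phase0_junctions = integer(), flank = 600L) {
  if (!is.null(seed)) set.seed(seed)
  for (attempt_prot in 1:40) {
    n_aa_target <- round(mean(exon_len_range) * n_exons / 3)
    protein <- .rand_protein(n_aa_target)
    cds_body <- .rev_translate(protein)
    cds <- paste0(cds_body, sample(c("TAA", "TAG", "TGA"), 1L))
    N <- nchar(cds)
    digest <- tryptic_digest_pos(protein, 2L, 7L, 35L)
    ok <- FALSE
    for (attempt_cut in 1:80) {
      if (n_exons == 1L) { cuts <- integer(); ok <- TRUE; break }
      lens <- sample(seq(exon_len_range[1L], exon_len_range[2L]),
                     n_exons, replace = TRUE)
      lens <- pmax(30L, round(lens * N / sum(lens)))
      cuts <- cumsum(lens)[seq_len(n_exons - 1L)]
      for (j in phase0_junctions) {
        cuts[j] <- cuts[j] - cuts[j] %% 3L
      }
      if (any(cuts <= 30L) || any(diff(c(0L, cuts, N)) < 30L)) next
      if (any(cuts >= N - 30L)) next
      # no exon after the first may start with G
      if (any(substring(cds, cuts + 1L, cuts + 1L) == "G")) next
      # every junction needs a bridging tryptic peptide
      if (!all(vapply(cuts, function(c)
        nrow(.bridging_rows(digest, c)) > 0L, logical(1)))) next
      ok <- TRUE
      break
    }
    if (ok) break
  }
  if (!ok) stop("generate_gene: could not satisfy junction constraints")

  bounds <- c(0L, cuts, N)
  introns <- character(n_exons - 1L)
  if (n_exons > 1L) {
    for (j in seq_len(n_exons - 1L)) {
      ilen <- sample(seq(intron_len_range[1L], intron_len_range[2L]), 1L)
      introns[j] <- paste0("GT", .rand_dna(ilen - 4L), "AG")
    }
  }
  seq_parts <- character()
  exon_start <- integer(n_exons); exon_end <- integer(n_exons)
  pos <- flank
  left <- .rand_dna(flank)
  seq_parts <- left
  for (i in seq_len(n_exons)) {
    ex_seq <- substr(cds, bounds[i] + 1L, bounds[i + 1L])
    exon_start[i] <- pos + 1L
    exon_end[i] <- pos + nchar(ex_seq)
    pos <- exon_end[i]
    seq_parts <- c(seq_parts, ex_seq)
    if (i < n_exons) {
      seq_parts <- c(seq_parts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  seq_parts <- c(seq_parts, .rand_dna(flank))
  contig <- paste(seq_parts, collapse = "")
  model <- gene_model(gene_id, data.frame(
    contig = contig_name, start = exon_start, end = exon_end, strand = "+"))
  list(seq = contig, model = model, protein = protein, cds = cds,
       junction_nt = cuts, introns = introns, digest = digest)
}

# flip a set of exon rows into the coordinates of the reverse-complemented
# contig of length L
.flip_exons <- function(ex, L, contig) {
  sel <- ex$contig == contig
  s <- ex$start[sel]; e <- ex$end[sel]
  ex$start[sel] <- L - e + 1L
  ex$end[sel] <- L - s + 1L
  ex$strand[sel] <- ifelse(ex$strand[sel] == "+", "-", "+")
  ex
}

# reverse-complement one contig of a scenario piece and remap every model
.flip_scenario_contig <- function(sc, contig) {
  L <- nchar(sc$contigs[[contig]])
  sc$contigs[[contig]] <- revcomp(sc$contigs[[contig]])
  if (!is.null(sc$truth_genome[[contig]])) {
    sc$truth_genome[[contig]] <- revcomp(sc$truth_genome[[contig]])
  }
  remap <- function(m) {
    m$exons <- .flip_exons(m$exons, L, contig)
    m$strand <- m$exons$strand[1L]
    # keep transcription order: exon rows on the flipped contig stay in
    # transcription order because start/end were mirrored rowwise
    validate_gene_model(m)
    m
  }
  sc$truth_models <- lapply(sc$truth_models, remap)
  sc$corrupted_models <- lapply(sc$corrupted_models, remap)
  if (!is.null(sc$manifest$inversion_interval) &&
      identical(sc$manifest$inversion_contig, contig)) {
    iv <- sc$manifest$inversion_interval
    sc$manifest$inversion_interval <- c(L - iv[2L] + 1L, L - iv[1L] + 1L)
  }
  sc
}

.submodel <- function(g, gene_id, exon_idx, strand = NULL, mrna_id = NULL) {
  ex <- g$model$exons[exon_idx, , drop = FALSE]
  if (!is.null(strand)) {
    ex$strand <- strand
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  }
  gene_model(gene_id, ex, mrna_id = mrna_id %||% paste0(gene_id, ".t1"))
}

# standard peptide evidence: all mc=0 products plus required bridges.
# `bridges` are wide-margin (>= 6 nt each side) junction peptides guaranteed
# by the generator; `crossing` lists every emitted peptide that touches the
# junction at all (>= 1 nt each side) — the set an ablation must withhold.
.standard_peptides <- function(g, junctions = seq_along(g$junction_nt)) {
  d <- g$digest
  peps <- d$peptide[d$mc == 0L]
  bridges <- list()
  for (j in junctions) {
    br <- .bridging_rows(d, g$junction_nt[j])
    bridges[[as.character(j)]] <- unique(br$peptide)
    peps <- c(peps, br$peptide)
  }
  peps <- unique(peps)
  crossing <- list()
  for (j in junctions) {
    cr <- unique(.bridging_rows(d, g$junction_nt[j], margin = 1L)$peptide)
    crossing[[as.character(j)]] <- intersect(cr, peps)
  }
  list(peptides = peps, bridges = bridges, crossing = crossing)
}

.scenario_A <- function() {
  g <- generate_gene(NULL, n_exons = 9L, gene_id = "tA", contig_name = "ctgA")
  d <- g$digest
  # hidden exon 8 and re-strandable exon 9 both need interior mc=0 peptides
  aa8 <- c(floor(g$junction_nt[7L] / 3) + 2L, ceiling(g$junction_nt[8L] / 3) - 1L)
  aa9 <- c(floor(g$junction_nt[8L] / 3) + 2L, nchar(g$protein) - 1L)
  if (!nrow(.interior_rows(d, aa8[1L], aa8[2L])) ||
      !nrow(.interior_rows(d, aa9[1L], aa9[2L]))) {
    stop("scenario A: no interior peptide")
  }
  ev <- .standard_peptides(g)
  corrupted <- list(
    .submodel(g, "gA1", 1:7),
    .submodel(g, "gA2", 9L, strand = "-"))
  list(contigs = list(ctgA = g$seq),
       truth_models = list(g$model),
       corrupted_models = corrupted,
       truth_proteins = c(PA = g$protein),
       transcripts = NULL,
       peptides = ev$peptides,
       manifest = list(
         scenario = "A", expected_correction = "merge",
         input_gene_ids = c("gA1", "gA2"), truth_gene_id = "tA",
         truth_protein_id = "PA",
         bridge_peptides = ev$bridges[c("7", "8")],
         ablation_peptides = ev$crossing[["7"]],
         evidence_tier = "protein"))
}

.scenario_B <- function() {
  g <- generate_gene(NULL, n_exons = 5L, gene_id = "tB", contig_name = "ctgB1")
  N <- nchar(g$cds)
  ex <- g$model$exons
  e5_len <- ex$end[5L] - ex$start[5L] + 1L
  # split the last exon: head stays on ctgB1, tail (with the stop) moves to
  # a small orphan contig, mimicking an assembly break
  c4 <- sum(ex$end[1:4] - ex$start[1:4] + 1L)  # CDS nt before exon 5
  ok_k <- integer()
  for (k in seq(30L, e5_len - 30L)) {
    if (nrow(.bridging_rows(g$digest, c4 + k))) ok_k <- c(ok_k, k)
  }
  if (!length(ok_k)) stop("scenario B: no bridging peptide over the break")
  k <- ok_k[sample.int(length(ok_k), 1L)]
  br <- unique(.bridging_rows(g$digest, c4 + k)$peptide)
  tail_len <- e5_len - k
  break_pos <- ex$start[5L] + k - 1L
  c1_seq <- substr(g$seq, 1L, break_pos)           # contig ends at the break
  tail_seq <- substr(g$seq, break_pos + 1L, ex$end[5L])
  c2_seq <- paste0(.rand_dna(250L), tail_seq, .rand_dna(250L))
  truth_ex <- rbind(
    ex[1:4, ],
    data.frame(contig = "ctgB1", start = ex$start[5L], end = break_pos,
               strand = "+"),
    data.frame(contig = "ctgB2", start = 251L, end = 250L + tail_len,
               strand = "+"))
  truth <- gene_model("tB", truth_ex)
  corrupt_ex <- truth_ex[1:5, ]
  corrupted <- gene_model("gB1", corrupt_ex)
  ev <- .standard_peptides(g)
  sc <- list(contigs = list(ctgB1 = c1_seq, ctgB2 = c2_seq),
             truth_models = list(truth),
             corrupted_models = list(corrupted),
             truth_proteins = c(PB = g$protein),
             transcripts = c(TRB = g$cds),
             peptides = unique(c(ev$peptides, br)),
             manifest = list(
               scenario = "B", expected_correction = "cross_contig_patch",
               input_gene_ids = "gB1", truth_gene_id = "tB",
               truth_protein_id = "PB",
               bridge_peptides = list(break_ = br),
               evidence_tier = "protein"))
  sc <- .flip_scenario_contig(sc, "ctgB1")
  .flip_scenario_contig(sc, "ctgB2")
}

.scenario_C <- function() {
  for (att in 1:30) {
    g <- generate_gene(NULL, n_exons = 9L, gene_id = "tC",
                       contig_name = "ctgC",
                       intron_len_range = c(180L, 300L))
    d <- g$digest
    aa9 <- c(floor(g$junction_nt[8L] / 3) + 2L, nchar(g$protein) - 1L)
    if (!nrow(.interior_rows(d, aa9[1L], aa9[2L]))) next
    # spurious exon: a stop-free-in-context window inside intron 8
    intr <- g$introns[8L]
    ilen <- nchar(intr)
    s_len <- 90L
    prefix8 <- substr(g$cds, 1L, g$junction_nt[8L])
    found <- NA_integer_
    for (off in seq(20L, ilen - s_len - 20L)) {
      s_seq <- substr(intr, off + 1L, off + s_len)
      if (!grepl("*", dna_translate(paste0(prefix8, s_seq)), fixed = TRUE)) {
        found <- off
        break
      }
    }
    if (is.na(found)) next
    ex <- g$model$exons
    s_start <- ex$end[8L] + found + 1L
    spur <- data.frame(contig = "ctgC", start = s_start,
                       end = s_start + s_len - 1L, strand = "+")
    corrupted <- gene_model("gC1", rbind(ex[1:8, ], spur))
    ev <- .standard_peptides(g, junctions = 1:8)
    sc <- list(contigs = list(ctgC = g$seq),
               truth_models = list(g$model),
               corrupted_models = list(corrupted),
               truth_proteins = c(PC = g$protein),
               transcripts = NULL,
               peptides = ev$peptides,
               manifest = list(
                 scenario = "C",
                 expected_correction = "terminal_exon_addition",
                 input_gene_ids = "gC1", truth_gene_id = "tC",
                 truth_protein_id = "PC",
                 bridge_peptides = ev$bridges["8"],
                 evidence_tier = "protein"))
    return(.flip_scenario_contig(sc, "ctgC"))
  }
  stop("scenario C: constraints not satisfied")
}

.scenario_D <- function() {
  g <- generate_gene(NULL, n_exons = 7L, gene_id = "tD",
                     contig_name = "ctgD1", phase0_junctions = c(3L, 4L))
  ex <- g$model$exons
  # native assembly split inside intron 3
  half <- ex$end[3L] + (ex$start[4L] - ex$end[3L]) %/% 2L
  c1_seq <- substr(g$seq, 1L, half)
  c2_seq <- substr(g$seq, half + 1L, nchar(g$seq))
  shift <- half
  ex2 <- ex
  ex2$contig[4:7] <- "ctgD2"
  ex2$start[4:7] <- ex$start[4:7] - shift
  ex2$end[4:7] <- ex$end[4:7] - shift
  truth <- gene_model("tD", ex2)
  corrupted <- list(
    gene_model("gD1", ex2[1:3, ]),
    gene_model("gD2", ex2[4L, , drop = FALSE]),
    gene_model("gD3", ex2[5:7, ]))
  ev <- .standard_peptides(g)
  list(contigs = list(ctgD1 = c1_seq, ctgD2 = c2_seq),
       truth_models = list(truth),
       corrupted_models = corrupted,
       truth_proteins = c(PD = g$protein),
       transcripts = NULL,
       peptides = ev$peptides,
       manifest = list(
         scenario = "D", expected_correction = "merge",
         input_gene_ids = c("gD1", "gD2", "gD3"), truth_gene_id = "tD",
         truth_protein_id = "PD",
         bridge_peptides = ev$bridges[c("3", "4")],
         evidence_tier = "protein"))
}

.scenario_E <- function() {
  g <- generate_gene(NULL, n_exons = 7L, gene_id = "tE",
                     contig_name = "ctgE1", phase0_junctions = 4L)
  d <- g$digest
  aa4 <- c(floor(g$junction_nt[3L] / 3) + 2L, ceiling(g$junction_nt[4L] / 3) - 1L)
  if (!nrow(.interior_rows(d, aa4[1L], aa4[2L]))) {
    stop("scenario E: no interior peptide in hidden exon")
  }
  ex <- g$model$exons
  # exon 7 is stranded on a second contig; ctgE1 keeps a junk tail
  c1_seq <- paste0(substr(g$seq, 1L, ex$end[6L] + 40L), .rand_dna(300L))
  ex7_seq <- substr(g$seq, ex$start[7L], ex$end[7L])
  c2_seq <- paste0(.rand_dna(250L), ex7_seq, .rand_dna(250L))
  truth_ex <- rbind(
    ex[1:6, ],
    data.frame(contig = "ctgE2", start = 251L,
               end = 250L + nchar(ex7_seq), strand = "+"))
  truth <- gene_model("tE", truth_ex)
  corrupted <- list(
    gene_model("gE1", ex[1:3, ]),
    gene_model("gE2", ex[5:6, ]))
  ev <- .standard_peptides(g)
  sc <- list(contigs = list(ctgE1 = c1_seq, ctgE2 = c2_seq),
             truth_models = list(truth),
             corrupted_models = corrupted,
             truth_proteins = c(PE = g$protein),
             transcripts = c(TRE = g$cds),
             peptides = ev$peptides,
             manifest = list(
               scenario = "E", expected_correction = "merge",
               input_gene_ids = c("gE1", "gE2"), truth_gene_id = "tE",
               truth_protein_id = "PE",
               bridge_peptides = ev$bridges[c("3", "4", "6")],
               evidence_tier = "protein"))
  sc <- .flip_scenario_contig(sc, "ctgE1")
  .flip_scenario_contig(sc, "ctgE2")
}

.scenario_F <- function() {
  g <- generate_gene(NULL, n_exons = 5L, gene_id = "tF",
                     contig_name = "ctgF", phase0_junctions = 2L)
  ex <- g$model$exons
  a <- ex$start[3L]; b <- ex$end[5L]
  seq0 <- g$seq
  inv_seq <- paste0(substr(seq0, 1L, a - 1L),
                    revcomp(substr(seq0, a, b)),
                    substr(seq0, b + 1L, nchar(seq0)))
  img <- function(p, q) c(a + b - q, a + b - p)
  img_ex <- t(vapply(3:5, function(i) img(ex$start[i], ex$end[i]),
                     numeric(2)))
  corrupted <- list(
    gene_model("gF1", ex[1:2, ]),
    gene_model("gF2", data.frame(contig = "ctgF", start = img_ex[, 1L],
                                 end = img_ex[, 2L], strand = "-")))
  sc <- list(contigs = list(ctgF = inv_seq),
             truth_genome = list(ctgF = seq0),
             truth_models = list(g$model),
             corrupted_models = corrupted,
             truth_proteins = c(PF = g$protein),
             transcripts = c(TRF = g$cds),
             peptides = character(),
             manifest = list(
               scenario = "F", expected_correction = "inversion_fix",
               input_gene_ids = c("gF1", "gF2"), truth_gene_id = "tF",
               truth_protein_id = "PF",
               inversion_interval = c(a, b), inversion_contig = "ctgF",
               evidence_tier = "transcript_only"))
  .flip_scenario_contig(sc, "ctgF")
}

.scenario_G <- function() {
  g <- generate_gene(NULL, n_exons = 8L, gene_id = "tG",
                     contig_name = "ctgG", phase0_junctions = 2L)
  corrupted <- list(.submodel(g, "gG1", 3:8))
  list(contigs = list(ctgG = g$seq),
       truth_models = list(g$model),
       corrupted_models = corrupted,
       truth_proteins = c(PG = g$protein),
       transcripts = c(TRG = g$cds),
       peptides = character(),
       manifest = list(
         scenario = "G", expected_correction = "upstream_exon_addition",
         input_gene_ids = "gG1", truth_gene_id = "tG",
         truth_protein_id = "PG",
         evidence_tier = "transcript_only"))
}

.scenario_H <- function() {
  for (att in 1:60) {
    g <- generate_gene(NULL, n_exons = 4L, gene_id = "tH",
                       contig_name = "ctgH", phase0_junctions = 2L)
    c2 <- g$junction_nt[2L]
    aa2 <- c2 %/% 3L                      # residues encoded by exons 1-2
    prot_res <- strsplit(g$protein, "")[[1L]]
    # need a cleavage site 3-6 residues before the junction so the retained
    # boundary peptide starts inside exon 2 and ends inside the retained
    # prefix
    win <- prot_res[(aa2 - 6L):(aa2 - 3L)]
    if (!any(win %in% c("K", "R"))) next
    if (any(prot_res[(aa2 - 2L):(aa2 + 1L)] %in% c("K", "R"))) next
    # retained prefix: 7 in-frame codons starting with the canonical GT
    # donor, a K at retained position 5, then the alternative GT donor
    ret_res <- c("V", sample(.CORE_AA, 3L, replace = TRUE), "K",
                 sample(.CORE_AA, 2L, replace = TRUE))
    ret_cod <- vapply(seq_along(ret_res), function(i) {
      if (i == 1L) {
        paste0("GT", sample(c("A", "C", "G", "T"), 1L))
      } else {
        cods <- .REV_CODON[[ret_res[i]]]
        cods[sample.int(length(cods), 1L)]
      }
    }, character(1))
    prefix21 <- paste(ret_cod, collapse = "")
    old_intron <- g$introns[2L]
    # rebuild intron 2: retained prefix + alternative donor + remainder;
    # reject if any later in-frame GT donor would allow a longer stop-free
    # retained segment (the maximal-prefix rule must pick 21 nt)
    ok <- FALSE
    for (att2 in 1:40) {
      rest <- paste0(.rand_dna(nchar(old_intron) - 25L), "AG")
      intron2 <- paste0(prefix21, "GT", rest)
      valid <- .valid_retention_lengths(intron2)
      if (length(valid) && max(valid) == 21L) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next
    # splice the new intron 2 into the contig
    ex <- g$model$exons
    pre <- substr(g$seq, 1L, ex$end[2L])
    post <- substr(g$seq, ex$start[3L], nchar(g$seq))
    delta <- nchar(intron2) - nchar(old_intron)
    contig <- paste0(pre, intron2, post)
    ex$start[3:4] <- ex$start[3:4] + delta
    ex$end[3:4] <- ex$end[3:4] + delta
    canonical <- gene_model("tH", ex, mrna_id = "tH.t1")
    ret_ex <- ex
    ret_ex$end[2L] <- ret_ex$end[2L] + 21L
    retained_model <- gene_model("tH", ret_ex, mrna_id = "tH.t2")
    genome1 <- c(ctgH = contig)
    retained_protein <- sub("\\*$", "",
                            spliced_cds(retained_model, genome1)$protein)
    # boundary peptide: crosses the exon2 | retained-intron2 junction and
    # ends inside the retained prefix (so its genomic match is contiguous)
    rd <- tryptic_digest_pos(retained_protein, 2L, 7L, 35L)
    cross <- rd[3L * (rd$start - 1L) + 1L <= c2 - 5L &
                  3L * rd$end >= c2 + 6L & 3L * rd$end <= c2 + 21L, ,
                drop = FALSE]
    if (!nrow(cross)) next
    ev <- .standard_peptides(g)
    return(list(
      contigs = list(ctgH = contig),
      truth_models = list(canonical, retained_model),
      corrupted_models = list(gene_model("gH1", ex, mrna_id = "gH1.t1")),
      truth_proteins = c(PH = g$protein),
      transcripts = NULL,
      peptides = unique(c(ev$peptides, cross$peptide)),
      manifest = list(
        scenario = "H", expected_correction = "intron_retention",
        input_gene_ids = "gH1", truth_gene_id = "tH",
        truth_protein_id = "PH",
        retained_protein = retained_protein,
        retained_intron_index = 2L, extra_residues = 7L,
        boundary_peptides = unique(cross$peptide),
        evidence_tier = "protein")))
  }
  stop("scenario H: constraints not satisfied")
}

# lengths p (multiples of 3) such that intron[1..p] is a stop-free in-frame
# retained segment bounded by an alternative canonical GT donor at p+1
.valid_retention_lengths <- function(intron_seq) {
  n <- nchar(intron_seq)
  ps <- seq(3L, n - 4L, by = 3L)
  ps[vapply(ps, function(p) {
    substr(intron_seq, p + 1L, p + 2L) == "GT" &&
      !grepl("*", dna_translate(substr(intron_seq, 1L, p)), fixed = TRUE)
  }, logical(1))]
}

#' Generate a scenario bundle
#'
#' Builds the default eight-scenario bundle (or a subset): a multi-contig
#' genome, true gene models, corrupted annotations realizing each anomaly
#' class, full-length protein evidence, transcripts where the corresponding
#' documented case was transcript-validated (B, E, F, G; F and G emit no
#' peptides and are therefore transcript-only genes), and a tryptic peptide
#' table guaranteed to contain the junction/novel-region peptides each
#' correction requires. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param classes subset of scenario classes to generate (default all 8).
#' @param decoy_rate fraction of additional decoy peptides absent from the
#'   genome (default 0).
#' @return a `scenario_bundle`: list with `genome`, `truth_models`,
#'   `corrupted_models`, `truth_proteins`, `transcripts`, `peptides`
#'   (data.frame), `manifest` (one entry per scenario), `seed`.
#' @export
generate_bundle <- function(seed = 42L, classes = .SCENARIO_CLASSES,
                            decoy_rate = 0) {
  stopifnot(all(classes %in% .SCENARIO_CLASSES))
  builders <- list(A = .scenario_A, B = .scenario_B, C = .scenario_C,
                   D = .scenario_D, E = .scenario_E, F = .scenario_F,
                   G = .scenario_G, H = .scenario_H)
  genome <- character()
  truth_genome_over <- character()
  truth_models <- list()
  corrupted_models <- list()
  truth_proteins <- character()
  transcripts <- character()
  pep_rows <- NULL
  manifest <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    sc <- NULL
    for (attempt in 0:24) {
      set.seed((seed %% 10000L) * 101L + ci * 1000L + attempt)
      sc <- tryCatch(builders[[cl]](), error = function(e) NULL)
      if (!is.null(sc) && .scenario_self_consistent(sc)) break
      sc <- NULL
    }
    if (is.null(sc)) stop("failed to generate scenario ", cl)
    genome <- c(genome, unlist(sc$contigs))
    if (!is.null(sc$truth_genome)) {
      truth_genome_over <- c(truth_genome_over, unlist(sc$truth_genome))
    }
    truth_models <- c(truth_models, sc$truth_models)
    corrupted_models <- c(corrupted_models, sc$corrupted_models)
    truth_proteins <- c(truth_proteins, sc$truth_proteins)
    if (!is.null(sc$transcripts)) transcripts <- c(transcripts, sc$transcripts)
    if (length(sc$peptides)) {
      pep_rows <- rbind(pep_rows, data.frame(
        peptide = sc$peptides,
        psm_count = sample(1:20, length(sc$peptides), replace = TRUE),
        source = "SYN-MS"))
    }
    manifest[[cl]] <- sc$manifest
  }
  peptides <- if (is.null(pep_rows)) {
    data.frame(peptide = character(), psm_count = integer(),
               source = character())
  } else {
    agg <- stats::aggregate(psm_count ~ peptide, data = pep_rows, FUN = sum)
    data.frame(peptide = agg$peptide, psm_count = agg$psm_count,
               source = "SYN-MS")[order(agg$peptide), ]
  }
  if (decoy_rate > 0 && nrow(peptides)) {
    n_dec <- max(1L, round(decoy_rate * nrow(peptides)))
    dec <- replicate(n_dec, paste(
      c(sample(.CORE_AA, 9L, replace = TRUE), "K"), collapse = ""))
    peptides <- rbind(peptides, data.frame(
      peptide = dec, psm_count = 1L, source = "DECOY"))
  }
  truth_genome <- genome
  truth_genome[names(truth_genome_over)] <- truth_genome_over
  structure(list(genome = genome, truth_genome = truth_genome,
                 truth_models = truth_models,
                 corrupted_models = corrupted_models,
                 truth_proteins = truth_proteins,
                 transcripts = transcripts, peptides = peptides,
                 manifest = manifest, seed = seed),
            class = "scenario_bundle")
}

# truth models must be internally consistent: spliced CDS starts ATG, ends
# with a stop, no internal stop. Truth coordinates refer to the restored
# genome where the scenario corrupts the assembly itself (inversion).
.scenario_self_consistent <- function(sc) {
  contigs <- sc$contigs
  for (nm in names(sc$truth_genome %||% list())) {
    contigs[[nm]] <- sc$truth_genome[[nm]]
  }
  genome <- unlist(contigs)
  all(vapply(sc$truth_models, function(m) {
    p <- spliced_cds(m, genome)$protein
    substr(p, 1L, 1L) == "M" && grepl("\\*$", p) &&
      !grepl("*", sub("\\*$", "", p), fixed = TRUE)
  }, logical(1)))
}

#' Write a scenario bundle to disk
#'
#' Emits genome.fasta, truth.gff3, corrupted.gff3, peptides.tsv,
#' transcripts.fasta, proteins.fasta and manifest.json under `dir`.
#'
#' @param bundle a `scenario_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$genome, file.path(dir, "genome.fasta"))
  write_gff3(bundle$truth_models, file.path(dir, "truth.gff3"))
  write_gff3(bundle$corrupted_models, file.path(dir, "corrupted.gff3"))
  write_peptides(bundle$peptides, file.path(dir, "peptides.tsv"))
  if (length(bundle$transcripts)) {
    write_fasta(bundle$transcripts, file.path(dir, "transcripts.fasta"))
  }
  write_fasta(bundle$truth_proteins, file.path(dir, "proteins.fasta"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
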