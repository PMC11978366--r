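test_that("integrity checks flag start/internal/stop defects in fixed order", {
  g <- c(c = "ATGAAATAAATGTAAAAATAAAAAAAAAA")
  mk <- function(s, e) gene_model("g", data.frame(contig = "c", start = s,
                                                  end = e, strand = "+"))
  expect_length(check_model_integrity(mk(1, 9), g), 0)
  an <- check_model_integrity(mk(1, 6), g)       # ATGAAA
  expect_equal(vapply(an, `[[`, character(1), "class"), "missing_stop")
  an2 <- check_model_integrity(mk(10, 21), g)    # ATGTAAAAATAA
  expect_equal(vapply(an2, `[[`, character(1), "class"), "internal_stop")
  an3 <- check_model_integrity(mk(4, 9), g)      # AAATAA
  expect_equal(vapply(an3, `[[`, character(1), "class"), "missing_start")
})

test_that("integrity checks are strand-invariant", {
  b <- get_bundle()
  for (m in b$corrupted_models[1:4]) {
    if (is_cross_contig(m)) next
    ctg <- m$contig
    L <- nchar(b$genome[[ctg]])
    g2 <- b$genome
    g2[[ctg]] <- revcomp(g2[[ctg]])
    ex <- m$exons
    s <- ex$start; e <- ex$end
    ex$start <- L - e + 1; ex$end <- L - s + 1
    ex$strand <- ifelse(ex$strand == "+", "-", "+")
    m2 <- gene_model(m$gene_id, ex, mrna_id = m$mrna_id)
    a1 <- sort(vapply(check_model_integrity(m, b$genome), `[[`,
                      character(1), "class"))
    a2 <- sort(vapply(check_model_integrity(m2, g2), `[[`,
                      character(1), "class"))
    expect_equal(a1, a2, info = m$gene_id)
  }
})

test_that("protein aligner reports identity, coverage and span", {
  al <- align_proteins("MKWHEDFYAA", "MKWHEDFYAA")
  expect_equal(al$identity, 1)
  expect_equal(al$coverage_query, 1)
  expect_equal(al$coverage_target, 1)

  target <- paste0(random_protein_str(0), "MKWHEDFYAACDEFGH")
  al2 <- align_proteins("MKWHEDFY", target)
  expect_equal(al2$identity, 1)
  expect_equal(al2$coverage_target, 0.5)
  expect_equal(al2$target_span, c(1, 8))
})

test_that("aligner score equals the full dynamic-programming oracle", {
  set.seed(31)
  for (rep in 1:10) {
    tl <- sample(40:150, 1)
    target <- random_protein_str(tl)
    a <- sample(seq_len(tl - 20), 1)
    b <- min(tl, a + sample(15:60, 1))
    query <- strsplit(substr(target, a, b), "")[[1]]
    # a couple of substitutions
    for (k in sample(seq_along(query), 2)) query[k] <- "W"
    query <- paste(query, collapse = "")
    al <- align_proteins(query, target)
    expect_equal(al$score, oracle_glocal_score(query, target))
  }
})

test_that("fragment relations are detected with trimming of spurious exons", {
  b <- get_bundle()
  # scenario D: three clean fragments of one protein
  d_models <- Filter(function(m) m$gene_id %in% c("gD1", "gD2", "gD3"),
                     b$corrupted_models)
  maps <- detect_fragment_relation(d_models, b$truth_proteins["PD"], b$genome)
  expect_length(maps, 1)
  expect_equal(nrow(maps[[1]]$placements), 3)
  expect_equal(maps[[1]]$placements$gene_id, c("gD1", "gD2", "gD3"))
  expect_true(maps[[1]]$combined_coverage >= 0.95)
  expect_true(all(diff(maps[[1]]$placements$span_start) > 0))

  # scenario C: trailing spurious exon must be trimmed away
  c_model <- Filter(function(m) m$gene_id == "gC1", b$corrupted_models)
  maps_c <- detect_fragment_relation(c_model, b$truth_proteins["PC"], b$genome)
  expect_length(maps_c, 1)
  expect_equal(maps_c[[1]]$placements$trimmed_exons, 1)

  # unrelated protein -> no fragment map
  none <- detect_fragment_relation(d_models,
                                   c(PX = random_protein_str(200)), b$genome)
  expect_length(none, 0)
})

test_that("placements never overlap by more than the tolerance", {
  b <- get_bundle()
  maps <- detect_fragment_relation(b$corrupted_models, b$truth_proteins,
                                   b$genome)
  for (mp in maps) {
    pl <- mp$placements
    if (nrow(pl) < 2) next
    expect_true(all(pl$span_start[-1] >= pl$span_end[-nrow(pl)] - 5))
  }
})

test_that("transcript chaining recovers exact exon boundaries", {
  set.seed(41)
  exon1 <- random_dna_str(80); exon2 <- random_dna_str(90)
  # avoid boundary micro-homology: intron starts GT, exon2 must not start G
  substr(exon2, 1, 1) <- "A"
  contig <- paste0(random_dna_str(100), exon1, "GT", random_dna_str(496),
                   "AG", exon2, random_dna_str(100))
  ch <- spliced_align_transcript(paste0(exon1, exon2), contig, "c", 20)
  expect_equal(nrow(ch$blocks), 2)
  expect_equal(ch$blocks$start, c(101, 101 + 80 + 500))
  expect_equal(ch$blocks$end, c(180, 100 + 80 + 500 + 90))
  expect_null(ch$unplaced)

  # middle third absent from the contig -> reported unplaced; first/last
  # bases chosen so chance micro-homology cannot shift the gap boundaries
  mid <- paste0("C", random_dna_str(57), "TT")
  ch2 <- spliced_align_transcript(paste0(exon1, mid, exon2), contig, "c", 20)
  expect_false(is.null(ch2$unplaced))
  expect_equal(c(ch2$unplaced$mrna_start, ch2$unplaced$mrna_end),
               c(81, 140))

  # reverse-complement contig -> minus-strand chain, same exons
  ch3 <- spliced_align_transcript(paste0(exon1, exon2), revcomp(contig),
                                  "c", 20)
  expect_true(all(ch3$blocks$strand == "-"))
  expect_equal(nrow(ch3$blocks), 2)
  L <- nchar(contig)
  expect_equal(ch3$blocks$start, L - c(180, 100 + 80 + 500 + 90) + 1)

  # truth reproduction on a generated scenario
  b <- get_bundle()
  tg <- b$manifest$G$truth_gene_id
  tm <- Filter(function(m) m$gene_id == tg, b$truth_models)[[1]]
  chG <- spliced_align_transcript(b$transcripts[["TRG"]],
                                  b$genome[[tm$contig]], tm$contig, 20)
  expect_equal(chG$blocks$start, tm$exons$start)
  expect_equal(chG$blocks$end, tm$exons$end)
})

test_that("inversion detection flags the exact inverted interval", {
  b <- get_bundle()
  man <- b$manifest$F
  fmods <- Filter(function(m) m$gene_id %in% man$input_gene_ids,
                  b$corrupted_models)
  ch <- spliced_align_transcript(b$transcripts[["TRF"]],
                                 b$genome[[man$inversion_contig]],
                                 man$inversion_contig, 20)
  inv <- detect_inversion(ch, fmods, man$inversion_contig)
  expect_length(inv, 1)
  expect_equal(inv[[1]]$class, "inversion")
  # one of the two strand-block spans is the true inverted interval
  ivs <- lapply(unique(ch$blocks$strand), function(s) {
    bb <- ch$blocks[ch$blocks$strand == s, ]
    c(min(bb$start), max(bb$end))
  })
  expect_true(any(vapply(ivs, function(iv)
    isTRUE(all.equal(iv, man$inversion_interval)), logical(1))))

  # consistent chain -> no anomaly
  chG <- spliced_align_transcript(b$transcripts[["TRG"]], b$genome[["ctgG"]],
                                  "ctgG", 20)
  expect_length(detect_inversion(chG, b$corrupted_models, "ctgG"), 0)
})
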