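test_that("annotated mapping places exonic and junction peptides exactly", {
  g <- c(c1 = "ATGAAATAA")
  m <- gene_model("g1", data.frame(contig = "c1", start = 1, end = 9,
                                   strand = "+"))
  h <- map_to_annotated("MK", list(m), g)
  expect_length(h, 1)
  expect_equal(h[[1]]$category, "exonic")
  expect_equal(sum(h[[1]]$blocks$end - h[[1]]$blocks$start + 1), 6)

  # peptide spanning the exon1/exon2 junction of the toy gene: MKTW|YEAVK
  tw <- toy_world()
  h2 <- map_to_annotated("TWYE", list(tw$model), tw$genome)
  expect_length(h2, 1)
  expect_equal(h2[[1]]$category, "junction")
  expect_equal(nrow(h2[[1]]$blocks), 2)
  expect_equal(h2[[1]]$blocks$end[1] - h2[[1]]$blocks$start[1] + 1, 6)
  expect_equal(h2[[1]]$blocks$end[2] - h2[[1]]$blocks$start[2] + 1, 6)
  # translating the concatenated blocks reproduces the peptide
  spliced <- paste0(
    seq_fetch(tw$genome, "chr", h2[[1]]$blocks$start[1],
              h2[[1]]$blocks$end[1], "+"),
    seq_fetch(tw$genome, "chr", h2[[1]]$blocks$start[2],
              h2[[1]]$blocks$end[2], "+"))
  expect_equal(dna_translate(spliced), "TWYE")
})

test_that("I/L equivalence is honoured and configurable", {
  g <- c(c1 = "ATGATTCTGAAATAA")  # M I L K *
  m <- gene_model("g1", data.frame(contig = "c1", start = 1, end = 15,
                                   strand = "+"))
  expect_length(map_to_annotated("MLIK", list(m), g, il_equivalent = TRUE), 1)
  expect_length(map_to_annotated("MLIK", list(m), g, il_equivalent = FALSE), 0)
})

test_that("genome search classifies novel, intron-retained and ambiguous hits", {
  tw <- toy_world()
  # peptide planted in intergenic space of a larger contig
  novel_cds <- "ATGGATTGGGAGTTTGGG"  # MDWEFG
  g <- c(chr = paste0(tw$genome[["chr"]], strrep("T", 30), novel_cds,
                      strrep("T", 30)))
  h <- map_to_genome("MDWEFG", g, list(tw$model))
  expect_length(h, 1)
  expect_equal(h[[1]]$category, "novel_region")

  # peptide crossing exon2 into the intron (toy intron codes CCC... = P)
  h2 <- map_to_genome("MKTWPP", c(chr = paste0(
    strrep("T", 10), substr(tw$cds, 1, 12), "CCCCCCCCCCCCCCCCCCCCCCAG",
    substr(tw$cds, 13, 30), strrep("T", 10))), list(tw$model))
  expect_length(h2, 1)
  expect_equal(h2[[1]]$category, "intron_retained")
  expect_equal(h2[[1]]$gene_id, "toy1")
  expect_equal(h2[[1]]$intron_index, 1)

  # multi-locus peptide -> every placement ambiguous
  g3 <- c(chr = paste0(strrep("T", 6), novel_cds, strrep("A", 9), novel_cds))
  h3 <- map_to_genome("MDWEFG", g3, list())
  expect_length(h3, 2)
  expect_true(all(vapply(h3, `[[`, character(1), "category") == "ambiguous"))
})

test_that("genome placements agree with the brute-force oracle", {
  set.seed(21)
  for (rep in 1:6) {
    s <- random_dna_str(900)
    sf <- six_frame_scan(s, 8, "c")
    if (!nrow(sf)) next
    r <- sf[sample(nrow(sf), 1), ]
    sub <- substr(r$protein, 1, min(9, nchar(r$protein)))
    got <- map_to_genome(sub, c(c = s), list(), il_equivalent = FALSE)
    want <- oracle_peptide_placements(sub, s)
    got_keys <- sort(vapply(got, function(h)
      paste(h$blocks$start, h$blocks$end, h$strand), character(1)))
    want_keys <- sort(paste(want$start, want$end, want$strand))
    expect_equal(got_keys, want_keys)
  }
})

test_that("all truth-derived peptides map against truth models (no unmapped)", {
  b <- get_bundle()
  hits <- classify_all(b$peptides, b$truth_models, b$truth_genome)
  cats <- vapply(hits, `[[`, character(1), "category")
  expect_false(any(cats == "unmapped"))
  # block-length conservation: every placed hit spans 3 x peptide length
  for (h in hits) {
    if (h$category == "unmapped") next
    expect_equal(sum(h$blocks$end - h$blocks$start + 1),
                 3 * nchar(h$peptide))
  }
})

test_that("classification is deterministic and annotated-first", {
  b <- get_bundle()
  h1 <- classify_all(b$peptides[1:25, ], b$corrupted_models, b$genome)
  h2 <- classify_all(b$peptides[1:25, ], b$corrupted_models, b$genome)
  expect_identical(hits_table(h1), hits_table(h2))
  expect_length(classify_all(b$peptides[0, ], b$corrupted_models, b$genome), 0)
})
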