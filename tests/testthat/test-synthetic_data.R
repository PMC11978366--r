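test_that("gene generation is deterministic and self-consistent", {
  g1 <- generate_gene(seed = 1, n_exons = 1L, gene_id = "g", contig_name = "c")
  expect_equal(nrow(g1$model$exons), 1)
  expect_equal(sub("\\*$", "", spliced_cds(g1$model,
                                           c(c = g1$seq))$protein),
               g1$protein)
  g1b <- generate_gene(seed = 1, n_exons = 1L, gene_id = "g",
                       contig_name = "c")
  expect_identical(g1$seq, g1b$seq)

  g9 <- generate_gene(seed = 3, n_exons = 9L, gene_id = "g", contig_name = "c")
  expect_equal(nrow(g9$model$exons), 9)
  expect_equal(sub("\\*$", "", spliced_cds(g9$model, c(c = g9$seq))$protein),
               g9$protein)
  # introns are canonical GT...AG
  for (intr in g9$introns) {
    expect_equal(substr(intr, 1, 2), "GT")
    expect_equal(substr(intr, nchar(intr) - 1, nchar(intr)), "AG")
  }
  # CDS starts ATG, single terminal stop, none internal
  expect_equal(substr(g9$cds, 1, 3), "ATG")
  prot_full <- dna_translate(g9$cds)
  expect_match(prot_full, "\\*$")
  expect_false(grepl("*", sub("\\*$", "", prot_full), fixed = TRUE))
})

test_that("bundles are deterministic under a fixed seed", {
  b1 <- generate_bundle(7)
  b2 <- generate_bundle(7)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$peptides, b2$peptides)
  expect_identical(b1$manifest, b2$manifest)
})

test_that("every truth model is clean and every corruption fails as prescribed", {
  b <- get_bundle()
  for (m in b$truth_models) {
    expect_length(check_model_integrity(m, b$truth_genome), 0)
  }
  classes <- function(gid) {
    m <- Filter(function(x) x$gene_id == gid, b$corrupted_models)[[1]]
    sort(vapply(check_model_integrity(m, b$genome), `[[`, character(1),
                "class"))
  }
  expect_equal(classes("gA1"), "missing_stop")          # split, no terminus
  expect_true("missing_stop" %in% classes("gB1"))       # truncated by break
  expect_equal(classes("gC1"), "missing_stop")          # spurious exon tail
  expect_equal(classes("gD1"), "missing_stop")
  expect_equal(classes("gD3"), "missing_start")
  expect_equal(classes("gF1"), "missing_stop")          # 3' half inverted
  expect_equal(classes("gG1"), "missing_start")         # upstream exons gone
  expect_length(check_model_integrity(
    Filter(function(x) x$gene_id == "gH1", b$corrupted_models)[[1]],
    b$genome), 0)                                       # H annotation is fine
})

test_that("scenario evidence contains the peptides each correction needs", {
  b <- get_bundle()
  peps <- b$peptides$peptide
  for (sc in c("A", "B", "C", "D", "E")) {
    br <- unlist(b$manifest[[sc]]$bridge_peptides)
    expect_true(all(br %in% peps), info = sc)
  }
  expect_true(all(b$manifest$H$boundary_peptides %in% peps))
  # transcript-only scenarios emit no peptides from their proteins
  for (sc in c("F", "G")) {
    prot <- b$truth_proteins[[b$manifest[[sc]]$truth_protein_id]]
    expect_false(any(vapply(peps, function(p)
      grepl(p, prot, fixed = TRUE), logical(1))), info = sc)
  }
})

test_that("decoy peptides are labelled and absent from the genome", {
  b <- generate_bundle(7, classes = c("A", "H"), decoy_rate = 0.1)
  dec <- b$peptides[b$peptides$source == "DECOY", ]
  expect_true(nrow(dec) >= 1)
  hits <- classify_all(dec, b$truth_models, b$truth_genome)
  expect_true(all(vapply(hits, `[[`, character(1), "category") %in%
                    c("unmapped", "ambiguous")))
})

test_that("subset bundles carry only the requested scenarios", {
  b <- generate_bundle(7, classes = c("A", "H"))
  expect_setequal(names(b$manifest), c("A", "H"))
  expect_equal(length(b$truth_proteins), 2)
})
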