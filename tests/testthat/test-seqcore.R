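test_that("translation follows the standard code, frames and N handling", {
  expect_equal(dna_translate("ATGGCTTAA"), "MA*")
  expect_equal(dna_translate("ATGGCTTAA", 1), "WL")  # TGG CTT, trailing AA dropped
  expect_equal(dna_translate("ATGNCT"), "MX")
  expect_equal(dna_translate(""), "")
  expect_equal(dna_translate("AT"), "")
})

test_that("translation agrees with the Biostrings oracle and respects frame shifts", {
  set.seed(11)
  for (rep in 1:10) {
    s <- random_dna_str(150 + sample(0:2, 1))
    for (off in 0:2) {
      expect_equal(dna_translate(s, off), oracle_translate(s, off))
      expect_equal(dna_translate(s, off),
                   dna_translate(substr(s, off + 1, nchar(s)), 0))
    }
  }
})

test_that("spliced CDS assembly handles both strands and cross-contig parts", {
  g <- c(c1 = "ATGAAATAA")
  m <- gene_model("g1", data.frame(contig = "c1", start = 1, end = 9,
                                   strand = "+"))
  expect_equal(spliced_cds(m, g)$protein, "MK*")

  tw <- toy_world()
  out <- spliced_cds(tw$model, tw$genome)
  expect_equal(out$mrna, tw$cds)
  expect_equal(out$protein, paste0(tw$protein, "*"))

  # two minus-strand exons whose reverse complements concatenate to the CDS
  part1 <- revcomp("ATGAAA"); part2 <- revcomp("TAA")
  ctg <- paste0("CC", part2, "GGGG", part1, "CC")
  g2 <- c(c2 = ctg)
  m2 <- gene_model("g2", data.frame(contig = "c2", start = c(10, 3),
                                    end = c(15, 5), strand = "-"))
  expect_equal(spliced_cds(m2, g2)$protein, "MK*")

  m_bad <- gene_model("g3", data.frame(contig = "c1", start = 5, end = 40,
                                       strand = "+"))
  expect_error(spliced_cds(m_bad, g), "out of bounds")
})

test_that("every generated truth model splices to its stored protein", {
  b <- get_bundle()
  for (m in b$truth_models) {
    p <- sub("\\*$", "", spliced_cds(m, b$truth_genome)$protein)
    if (m$mrna_id == "tH.t2") {
      expect_equal(p, b$manifest$H$retained_protein)
    } else {
      pid <- NULL
      for (sc in names(b$manifest)) {
        if (b$manifest[[sc]]$truth_gene_id == m$gene_id) {
          pid <- b$manifest[[sc]]$truth_protein_id
        }
      }
      expect_equal(p, unname(b$truth_proteins[pid]), info = m$gene_id)
    }
  }
})

test_that("tryptic digestion applies the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("MKRAPK", 0, 1, 50), c("MK", "R", "APK"))
  expect_equal(tryptic_digest("AKPR", 0, 1, 50), "AKPR")
  expect_setequal(tryptic_digest("MKRAPK", 1, 1, 50),
                  c("MK", "R", "APK", "MKR", "RAPK"))
  expect_equal(tryptic_digest("", 0), character())
  expect_error(tryptic_digest("MK*AK", 0), "stop")
})

test_that("mc=0 digestion partitions the protein (reconstruction property)", {
  set.seed(5)
  for (rep in 1:12) {
    prot <- random_protein_str(sample(30:200, 1))
    pieces <- tryptic_digest(prot, 0, 1, 10000)
    expect_equal(paste(pieces, collapse = ""), prot)
    pos <- tryptic_digest_pos(prot, 2, 1, 10000)
    expect_true(all(substring(prot, pos$start, pos$end) == pos$peptide))
  }
})

test_that("six-frame scan finds ORF stretches with exact projection", {
  sf <- six_frame_scan("ATGAAATAA", 2, "c1")
  plus0 <- sf[sf$strand == "+" & sf$frame == 0, ]
  expect_equal(plus0$protein, "MK")
  expect_equal(c(plus0$start, plus0$end), c(1, 6))
  # strand symmetry
  sf_rc <- six_frame_scan(revcomp("ATGAAATAA"), 2, "c1")
  minus0 <- sf_rc[sf_rc$strand == "-" & sf_rc$protein == "MK", ]
  expect_equal(nrow(minus0), 1)
})

test_that("six-frame scan equals the brute-force oracle on random contigs", {
  set.seed(99)
  for (rep in 1:8) {
    s <- random_dna_str(600)
    expect_equal(six_frame_scan(s, 8, "c"), oracle_six_frame(s, 8, "c"))
  }
})

test_that("splice-site discovery reports canonical dinucleotides", {
  ss <- find_splice_sites("AAGTAA")
  don <- ss[ss$kind == "donor" & ss$strand == "+", ]
  expect_equal(don$position, 3)
  ss2 <- find_splice_sites("AAAGAA")
  acc <- ss2[ss2$kind == "acceptor" & ss2$strand == "+", ]
  expect_equal(acc$position, 4)
  expect_equal(nrow(find_splice_sites("AAAAAA")), 0)
  # minus-strand orientation: genomic AC is a minus-strand donor GT
  ss3 <- find_splice_sites("TTACTT")
  expect_true(any(ss3$kind == "donor" & ss3$strand == "-"))
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("g", data.frame(contig = "c", start = c(1, 5),
                                          end = c(10, 20), strand = "+")),
               "overlapping")
  expect_error(gene_model("g", data.frame(contig = "c", start = c(10, 1),
                                          end = c(20, 5), strand = "+")),
               "order")
  expect_error(gene_model("g", data.frame(contig = "c", start = 5, end = 2,
                                          strand = "+")), "invalid")
  tw <- toy_world()
  intr <- proteorefine:::model_introns(tw$model)
  expect_equal(nrow(intr), 1)
  expect_equal(c(intr$start, intr$end), c(23, 46))
  fl <- model_flags(tw$model, tw$genome)
  expect_true(fl$has_start && fl$has_stop)
})
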