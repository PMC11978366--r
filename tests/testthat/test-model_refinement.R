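test_that("novel exon inference extends peptide support to canonical sites", {
  # intergenic ORF flanked by AG ... GT, one supporting peptide
  inner <- "ATGGATTGGGAGTTTGGGCATCAT"   # MDWEFGHH
  contig <- paste0(strrep("T", 40), "AG", inner, "GT", strrep("T", 40))
  genome <- c(c = contig)
  hits <- map_to_genome("DWEFG", genome, list())
  expect_length(hits, 1)
  ex <- infer_novel_exon(hits, genome)
  expect_equal(nrow(ex), 1)
  expect_equal(ex$start, 43)                 # first base after the AG
  expect_equal(ex$end, 42 + nchar(inner))    # last base before the GT

  # terminal exon: extend to the first in-frame stop
  contig2 <- paste0(strrep("T", 40), "AG", inner, "TAACCCCCC")
  ex2 <- infer_novel_exon(map_to_genome("DWEFG", c(c = contig2), list()),
                          c(c = contig2), terminal = TRUE)
  expect_equal(ex2$end, 42 + nchar(inner) + 3)  # includes the TAA

  # no canonical boundary within the window -> unresolved (zero rows)
  contig3 <- paste0(strrep("T", 40), inner, strrep("T", 40))
  ex3 <- infer_novel_exon(map_to_genome("DWEFG", c(c = contig3), list()),
                          c(c = contig3), window = 30)
  expect_equal(nrow(ex3), 0)
})

test_that("intron retention is called with the documented 7-residue case", {
  b <- get_bundle()
  man <- b$manifest$H
  model <- Filter(function(m) m$gene_id == "gH1", b$corrupted_models)[[1]]
  hits <- classify_all(b$peptides, b$corrupted_models, b$genome)
  ir <- Filter(function(h) h$category == "intron_retained" &&
                 identical(h$gene_id, "gH1"), hits)
  expect_true(length(ir) >= 1)
  res <- call_intron_retention(model, ir, b$genome)
  expect_false(is.null(res$pair))
  expect_equal(res$pair$extra_residues, 7)
  expect_equal(res$pair$retained_intron_index, man$retained_intron_index)
  expect_equal(res$pair$retained, man$retained_protein)
  expect_equal(res$pair$canonical, unname(b$truth_proteins["PH"]))
  # retained proteoform differs from canonical by an in-frame insertion
  expect_equal(nchar(res$pair$retained) - nchar(res$pair$canonical), 7)
})

test_that("retention is refused when the retained prefix hits a stop", {
  # gene M K T W | intron starting GT with an in-frame stop before any
  # alternative donor
  cds1 <- "ATGAAAACTTGG"; cds2 <- "TATGAAGCTGTAAAATAA"
  intron <- paste0("GTTTAA", strrep("C", 14), "AG")  # GTT TAA -> stop
  contig <- paste0(strrep("T", 10), cds1, intron, cds2, strrep("T", 10))
  genome <- c(chr = contig)
  model <- gene_model("t1", data.frame(
    contig = "chr", start = c(11, 11 + 12 + 22), end = c(22, 10 + 12 + 22 + 18),
    strand = "+"))
  fake_hit <- list(peptide = "KTWV", psm_count = 1, contig = "chr",
                   strand = "+", gene_id = "t1", intron_index = 1,
                   blocks = data.frame(contig = "chr", start = 14, end = 25,
                                       strand = "+"),
                   category = "intron_retained")
  res <- call_intron_retention(model, list(fake_hit), genome)
  expect_false(is.null(res$unresolved))

  # evidence entirely within the exon does not support a call
  inside <- fake_hit
  inside$blocks <- data.frame(contig = "chr", start = 11, end = 22,
                              strand = "+")
  expect_null(call_intron_retention(model, list(inside), genome))
})

test_that("merging rejects fragment sets without junction support", {
  b <- get_bundle()
  man <- b$manifest$A
  a_models <- Filter(function(m) m$gene_id %in% man$input_gene_ids,
                     b$corrupted_models)
  maps <- detect_fragment_relation(a_models, b$truth_proteins["PA"], b$genome)
  expect_length(maps, 1)
  # withhold every junction-crossing peptide: the merge must not go through
  keep <- setdiff(b$peptides$peptide, unlist(man$bridge_peptides))
  keep <- setdiff(keep, unlist(man$ablation_peptides))
  hits <- classify_all(b$peptides[b$peptides$peptide %in% keep, ],
                       a_models, b$genome)
  res <- merge_models(a_models, maps[[1]], b$genome, b$truth_proteins,
                      hits, keep)
  expect_false(is.null(res$unresolved))

  # with full evidence the same call reconstructs the truth protein
  hits_full <- classify_all(b$peptides, a_models, b$genome)
  res2 <- merge_models(a_models, maps[[1]], b$genome, b$truth_proteins,
                       hits_full, b$peptides$peptide)
  expect_null(res2$unresolved)
  expect_equal(res2$record$class, "merge")
  expect_equal(sub("\\*$", "", spliced_cds(res2$model, b$genome)$protein),
               unname(b$truth_proteins["PA"]))
})

test_that("inversion correction restores the assembly and is a no-op otherwise", {
  b <- get_bundle()
  man <- b$manifest$F
  ctg <- man$inversion_contig
  fmods <- Filter(function(m) m$gene_id %in% man$input_gene_ids,
                  b$corrupted_models)
  ch <- spliced_align_transcript(b$transcripts[["TRF"]], b$genome[[ctg]],
                                 ctg, 20)
  ch$mrna <- b$transcripts[["TRF"]]
  inv <- detect_inversion(ch, fmods, ctg)
  fix <- correct_inversion(b$genome, inv[[1]], fmods)
  expect_true(fix$ok)
  # flipping the flagged block back restores the pre-corruption contig
  expect_equal(fix$genome[[ctg]], b$truth_genome[[ctg]])
  # remapped models are strand-consistent with the truth gene
  strands <- unlist(lapply(fix$models, function(m) m$exons$strand))
  expect_equal(length(unique(strands)), 1)

  # a consistent chain produces no anomaly, so there is nothing to correct
  chG <- spliced_align_transcript(b$transcripts[["TRG"]], b$genome[["ctgG"]],
                                  "ctgG", 20)
  expect_length(detect_inversion(chG, b$corrupted_models, "ctgG"), 0)
})

test_that("upstream exon addition extends the model 5' from the chain", {
  b <- get_bundle()
  tm <- Filter(function(m) m$gene_id == b$manifest$G$truth_gene_id,
               b$truth_models)[[1]]
  g1 <- Filter(function(m) m$gene_id == "gG1", b$corrupted_models)[[1]]
  ch <- spliced_align_transcript(b$transcripts[["TRG"]],
                                 b$genome[[tm$contig]], tm$contig, 20)
  chain_ex <- data.frame(contig = tm$contig, start = ch$blocks$start,
                         end = ch$blocks$end, strand = ch$blocks$strand)
  res <- add_upstream_exons(g1, chain_ex, b$genome)
  expect_equal(res$record$class, "upstream_exon_addition")
  expect_equal(nrow(res$model$exons), 8)
  expect_true(res$has_start)
  expect_equal(sub("\\*$", "", spliced_cds(res$model, b$genome)$protein),
               unname(b$truth_proteins["PG"]))
  # chain identical to the model -> no record
  expect_null(add_upstream_exons(res$model, chain_ex, b$genome))
})

test_that("evidence ablation never creates new corrections (monotonicity)", {
  b <- get_bundle()
  full <- get_refined()
  full_keys <- sort(paste(full$ledger$class, full$ledger$input_gene_ids))
  set.seed(77)
  drop <- sample(nrow(b$peptides), round(0.3 * nrow(b$peptides)))
  sub <- b$peptides[-drop, ]
  res <- refine_all(b$genome, b$corrupted_models, sub, b$truth_proteins,
                    b$transcripts)
  sub_keys <- sort(paste(res$ledger$class, res$ledger$input_gene_ids))
  expect_true(all(sub_keys %in% full_keys))
})
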