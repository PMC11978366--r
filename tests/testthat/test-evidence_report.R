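test_that("evidence tiers follow the peptide > transcript > none hierarchy", {
  expect_equal(assign_evidence_tier("g", 3, character())$tier, "protein")
  expect_equal(assign_evidence_tier("g", 0, "Rp-1")$tier, "transcript_only")
  expect_equal(assign_evidence_tier("g", 0, character())$tier, "none")
  # ambiguous-only peptide evidence does not reach protein tier: the caller
  # counts unambiguous peptides, so such a gene falls through to transcript
  expect_equal(assign_evidence_tier("g", 0, "Rp-2",
                                    status = "gene")$tier, "transcript_only")
})

test_that("ledger summary enforces its bookkeeping identities", {
  ledger <- data.frame(class = c("merge", "intron_retention"),
                       input_gene_ids = c("a,b", "c"),
                       output_gene_id = c("a", "c"),
                       output_mrna_id = c("a.t1", "c.t2"),
                       n_inputs = c(2L, 1L), detail = "")
  ev <- rbind(assign_evidence_tier("a", 2),
              assign_evidence_tier("c", 1),
              assign_evidence_tier("d", 0, "tr1"))
  s <- summarize_refinement(ledger, ev, 4L)
  expect_equal(s$n_genes_after, 3)
  expect_equal(s$n_corrections, 1)   # intron retention not counted
  expect_equal(s$n_merged_away, 1)
  expect_equal(s$n_protein_tier, 2)
  expect_equal(s$n_transcript_only_tier, 1)

  # inconsistent inputs are rejected
  expect_error(summarize_refinement(ledger, ev, 10L), "bookkeeping")
})

test_that("summary is invariant to row order", {
  b <- get_bundle()
  res <- get_refined()
  ev <- res$evidence
  set.seed(1)
  s1 <- summarize_refinement(res$ledger, ev, 13L)
  s2 <- summarize_refinement(res$ledger[rev(seq_len(nrow(res$ledger))), ],
                             ev[sample(nrow(ev)), ], 13L)
  expect_equal(s1, s2)
})

test_that("empty ledger keeps the gene count unchanged", {
  ev <- rbind(assign_evidence_tier("a", 1), assign_evidence_tier("b", 1))
  s <- summarize_refinement(ledger_table(list()), ev, 2L)
  expect_equal(s$n_genes_after, s$n_genes_before)
  expect_equal(s$n_corrections, 0)
})

test_that("the packaged gene table reproduces the published bookkeeping", {
  fx <- load_gene_table_fixture()
  expect_equal(nrow(fx), 17)
  s <- gene_table_summary(fx)
  expect_equal(s$n_genes_after, 15)
  expect_equal(s$n_corrections, 7)
  expect_equal(s$n_protein_tier, 11)
  expect_equal(s$n_transcript_only_tier, 2)
  expect_equal(s$n_no_evidence, 2)
  expect_equal(s$n_putative_fragments, 2)
})
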