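# Shared fixtures: the default scenario bundle and its refinement are
# generated once per test session and reused across files (generation and
# the full pipeline each take a few seconds).

.fixture_env <- new.env(parent = emptyenv())

get_bundle <- function(seed = 42L) {
  key <- paste0("bundle_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_bundle(seed)
  }
  .fixture_env[[key]]
}

get_refined <- function(seed = 42L) {
  key <- paste0("refined_", seed)
  if (is.null(.fixture_env[[key]])) {
    b <- get_bundle(seed)
    .fixture_env[[key]] <- refine_all(b$genome, b$corrupted_models,
                                      b$peptides, b$truth_proteins,
                                      b$transcripts)
  }
  .fixture_env[[key]]
}

# record matching one scenario's manifest entry (by input gene-id set)
scenario_record <- function(result, manifest_entry) {
  Filter(function(r) setequal(r$input_gene_ids, manifest_entry$input_gene_ids),
         result$records)
}

# a tiny single-contig, single-gene world used by toy tests:
# gene MKTWYEAVK* with one intron between codon-aligned exons
toy_world <- function() {
  # CDS: ATG AAA ACT TGG TAT GAA GCT GTA AAA TAA -> MKTWYEAVK*
  cds <- "ATGAAAACTTGGTATGAAGCTGTAAAATAA"
  exon1 <- substr(cds, 1, 12)
  exon2 <- substr(cds, 13, 30)
  intron <- paste0("GT", strrep("C", 20), "AG")
  contig <- paste0(strrep("T", 10), exon1, intron, exon2, strrep("T", 10))
  genome <- c(chr = contig)
  model <- gene_model("toy1", data.frame(
    contig = "chr", start = c(11, 11 + 12 + 24), end = c(22, 10 + 12 + 24 + 18),
    strand = "+"))
  list(genome = genome, model = model, cds = cds, protein = "MKTWYEAVK")
}
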