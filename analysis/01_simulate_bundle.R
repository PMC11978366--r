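#!/usr/bin/env Rscript
# Step 1 — simulate the study conditions.
#
# Builds the default eight-scenario bundle: a multi-contig toy genome whose
# annotation is corrupted with each documented anomaly class (split genes,
# hidden exons, cross-contig fragments, an inverted assembly block, missing
# upstream exons, an intron-retention proteoform), together with the
# evidence a proteogenomic reannotation uses: tryptic MS peptides,
# digestive-transcript sequences and full-length protein entries.
# Everything is written as plain FASTA/GFF3/TSV under results/bundle/.

suppressPackageStartupMessages(library(proteorefine))

seed <- 42L
out <- "results/bundle"
bundle <- generate_bundle(seed)
write_bundle(bundle, out)

cat(sprintf("Bundle (seed %d): %d contigs, %d nt genome\n", seed,
            length(bundle$genome), sum(nchar(bundle$genome))))
cat(sprintf("  %d true genes -> %d corrupted models\n",
            length(unique(vapply(bundle$truth_models, `[[`, character(1),
                                 "gene_id"))),
            length(bundle$corrupted_models)))
cat(sprintf("  evidence: %d peptides, %d transcripts, %d proteins\n",
            nrow(bundle$peptides), length(bundle$transcripts),
            length(bundle$truth_proteins)))
cat("Injected anomaly classes:\n")
for (sc in names(bundle$manifest)) {
  man <- bundle$manifest[[sc]]
  cat(sprintf("  %s: %-24s genes %s\n", sc, man$expected_correction,
              paste(man$input_gene_ids, collapse = ",")))
}
cat("Files written under", out, "\n")
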