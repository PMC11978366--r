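Package: proteorefine
Title: Proteogenomic Refinement of Gene Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps MS/MS-identified peptides, full-length protein evidence and
    transcript evidence onto an annotated genome to detect and repair gene-model
    anomalies: missing stop codons, gene models fragmented across loci or
    contigs, unannotated exons, misclassified introns, inverted assembly blocks
    and intron-retention proteoforms. Includes a synthetic-genome generator that
    injects each documented anomaly class with known ground truth, so the whole
    refinement pipeline is verifiable without external downloads, plus
    bookkeeping utilities that tier each gene by expression evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
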