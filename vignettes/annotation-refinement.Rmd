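---
title: "Proteogenomic gene-model refinement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic gene-model refinement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteorefine)
```

## The problem

Draft-genome annotations of large, repetitive gene families are often
wrong in characteristic ways: a single gene annotated as two or three
independent fragments, exons hidden in what the annotation calls
intergenic sequence, intronic sequence misclassified as a coding exon,
exons stranded on the wrong contig by an assembly break, whole blocks
assembled in inverted orientation, and truncated 5' ends. Peptides
sequenced by tandem MS are direct observations of the true protein
products, so mapping them back onto the genome — together with full-length
protein entries and transcript sequences — lets each of these defects be
detected and repaired. This package implements that reannotation procedure
as a deterministic pipeline, with a synthetic-genome generator that
injects every anomaly class so the pipeline can be validated end-to-end
against known truth.

## Evidence model

Three evidence channels drive corrections, in decreasing strength:

* **Junction peptides.** A peptide whose codons span two exons proves the
  exons belong to one transcript, and — because its residues must continue
  correctly across the splice — pins the junction coordinates. A single
  unambiguous junction peptide is accepted as sufficient evidence
  (`min_peptides = 1`): the underlying study design validates exons with
  single shared peptides, and requiring more would only discard true
  repairs on low-coverage proteins.
* **Transcript chains.** Transcripts are placed by greedy maximal
  exact-match chaining (`spliced_align_transcript()`, minimum block 20 nt).
  Because the evidence in this setting is same-genome and near-exact, exact
  matching replaces a heuristic spliced aligner and keeps results
  deterministic. Chain blocks give exon boundaries directly; mRNA segments
  that cannot be placed on the subject contig are searched on all other
  contigs and become cross-contig patches.
* **Full-length proteins.** Model-encoded proteins are aligned to
  full-length evidence entries query-globally against a local target
  region, with fixed scoring (match +2, mismatch −1, gap open −5, extend
  −1). The external tools behind such evidence are normally run "with
  default parameters"; fixing one internal scoring scheme keeps the
  artifact reproducible. Fragment relations require identity ≥ 0.95 and
  fragment coverage ≥ 0.9, with ≤ 5 residues of overlap between ordered
  placements (signal-peptide/propeptide fuzz); the strict defaults reflect
  that the motivating cases are near-identity matches, not remote homology.

Isoleucine and leucine are isobaric and indistinguishable by standard MS,
so peptide matching folds I to L by default (`il_equivalent = TRUE`).
Peptides that place at more than one genomic locus are downgraded to
*ambiguous* and never used as refinement evidence (they are still
reported); this conservative rule prevents chimeric merges at the cost of
ignoring genuinely repeated loci.

## Pipeline stages and their order

`refine_all()` runs a fixed stage order: integrity checks → peptide
mapping → inversion fixes → fragment detection → transcript-driven
consolidation (merges, cross-contig patches, upstream additions) →
peptide-driven consolidation (merges, novel and terminal exons) → intron
retention → ledger. Inversion fixes come before any merging because a
merge across an inverted block is only visible after re-stranding.
Transcript-driven corrections run before peptide-driven ones because a
colinear transcript chain determines every exon boundary at once; peptide
inference is the fallback where no transcript covers the locus. Peptide
hits are re-classified after each consolidation stage so later stages see
the corrected annotation.

Novel-exon boundaries deserve detail. A cluster of *novel-region* hits
gives only the peptide-supported interval. The 5' boundary is sought among
genomic positions immediately preceded by a canonical acceptor `AG`
within a 300-nt window (and up to 9 nt inside the cluster, since a
placement in a shifted reading frame can overhang the true exon by a base
or two); each candidate is accepted only if some still-unmapped peptide
maps across the junction it would create, scanning candidates from the
nearest outward. The 3' boundary is pinned the same way against `GT`
donors, or — for a terminal exon — extended to the first in-frame stop
codon. Ties between equally supported candidates resolve toward the longer
exon, which keeps the peptide evidence interior. If no candidate boundary
is supported by a junction peptide the case is left *unresolved* rather
than guessed: removing evidence can only remove corrections, never add
them (this monotonicity is property-tested).

An inversion is flagged when a transcript chain needs both strands of one
contig. Either strand-block span could in principle be the inverted
segment; the pipeline tries the flagged (minority) interval first,
re-chains the transcript on the re-complemented contig, and keeps the
orientation that makes the chain single-strand and colinear. Corrected
coordinates refer to the repaired assembly, which is returned alongside
the models.

Intron retention requires a peptide placement crossing an exon/intron
boundary in frame. The retained segment is the maximal stop-free intronic
prefix whose length is divisible by 3 and which ends at an alternative
canonical `GT` donor; retention that would introduce an in-frame stop, or
leave the downstream frame shifted, is refused. The call emits both
proteoforms as two mRNAs of one gene, so a second pipeline pass sees the
boundary peptide as ordinary junction evidence — this is what makes the
pipeline idempotent. A retention characterization documents a proteoform
rather than fixing a wrong model, so the bookkeeping counts it in the
ledger but not among annotation corrections.

Where one documented case combines several repairs (a terminal exon plus a
misclassified-intron removal; a merge plus a hidden internal exon plus a
cross-contig patch; an inversion plus the merge it unblocks), the pipeline
emits **one** consolidated record whose class names the primary
correction and whose detail itemizes the sub-events. The unit of counting
is thus "one corrected gene annotation", matching how such corrections are
reported in practice.

## Coordinates and formats

External formats are GFF3 (1-based, inclusive) and FASTA; peptides arrive
as a plain TSV (`peptide`, `psm_count`, `source`) — spectra and PSM
rescoring are upstream concerns. Internally all interval arithmetic is
1-based inclusive, the native convention of R and of the Bioconductor
range containers; conversion to BED's 0-based half-open happens only in
the BED exporter. A gene repaired across an assembly gap is serialized as
one mRNA per contig sharing the gene ID with `part=` attributes, and
re-assembled on parsing. `N` bases are legal genome content (draft
assemblies contain unsequenced runs); codons containing `N` translate to
`X`. Models supplied as CDS-only or exon-only are both accepted; CDS wins
when both are present.

## The synthetic bundle: what it emulates and what it does not

`generate_bundle(seed)` builds eight independent scenarios on separate
contigs (~25 kb total), one per anomaly class: (A) a gene split in two
with a hidden intergenic exon and a wrong-strand single-exon fragment;
(B) a terminal-exon fragment stranded on an orphan contig; (C) a missing
terminal exon plus intronic sequence annotated as a ninth exon; (D) a
three-way split of a gene natively spanning two contigs; (E) adjacent
fragments with an unannotated internal exon and a C-terminal exon on
another contig; (F) an inverted block containing a wrong-strand model;
(G) two missing upstream exons; (H) an intron-retention proteoform with a
21-nt retained prefix — 7 extra residues, mirroring the documented case.
Default gene shapes follow the documented outcomes (the scenario-A gene
has 9 exons, the scenario-G gene 8).

Generated CDS begin with ATG, end with a single stop and are stop-free
internally by construction — codons are sampled from real-residue codon
sets, never edited post hoc. Introns are canonical `GT…AG`. Proteins are
drawn from a uniform residue alphabet without proline, and K/R are placed
every 8–14 residues, so tryptic digestion (cleave after K/R unless before
P; up to 2 missed cleavages; peptide length 7–35, common search-engine
defaults) yields a peptide crossing every junction; the KP-exception code
path is exercised by literal-string unit tests instead. No exon after the
first begins with G, so exact-match chaining cannot overshoot a boundary
through micro-homology with the `GT` donor. Evidence channels mirror the
documented cases: scenarios B, E, F and G carry transcripts; F and G emit
no peptides and therefore end as transcript-only genes; A, C, D and H are
peptide-driven. Intergenic padding is ≥ 500 nt so windowed boundary
searches cannot leak across genes.

The generator emulates annotation and assembly pathology, not measurement
noise: there are no mass errors, modified residues, decoy-level false
identifications (unless `decoy_rate > 0`, which adds genome-absent
peptides), non-canonical splice sites, or repeat-induced ambiguous loci.
Passing the synthetic suite therefore demonstrates the *logic* of
detection and repair under clean evidence — it does not certify
performance on noisy real data, where ambiguous placements and
non-canonical junctions would route more cases into the unresolved list.

## Numerical and degenerate-input choices

Exact string matching underlies peptide placement and transcript chaining,
so there are no floating-point tolerances in the core; the only thresholds
are the alignment identity/coverage gates above. The six-frame scan
reports maximal stop-free stretches of ≥ 8 residues (the shortest credible
tryptic evidence). Degenerate inputs fail loudly at the I/O boundary:
empty FASTA records, non-residue characters in the peptide table and
orphaned GFF3 features are errors naming the offending line or row. A
mixed-strand mRNA is an error by default, but can be downgraded to a
warning — strand disagreement within one transcript is itself the
signature of the inversion anomaly, and the caller may want the model
loaded for exactly that diagnosis.

Problem sizes were chosen to keep the full validation loop interactive:
the default bundle refines in a few seconds, and the complete test suite
(including brute-force oracle comparisons for the six-frame scan, peptide
placement and the aligner on random sequences, and three full pipeline
runs) finishes in under two minutes on one CPU.

## The worked-example catalogue

`inst/extdata/rprolixus_a1_genes.tsv` transcribes the published catalogue
of the *Rhodnius prolixus* A1 aspartic-protease family: 17 final entries
carrying 23 pre-correction gene identifiers, merge groups, genomic
locations, transcript/protein accessions, masses (in daltons, despite the
original column header's kDa label), per-gene evidence flags and
putative-fragment status. `gene_table_summary()` rebuilds a ledger and
evidence table from it and reproduces the printed bookkeeping — 15 final
genes, 7 corrections, 11 protein-tier genes, 2 transcript-only — without
any download. Two flags are inferences rather than explicit statements in
the source: the identity of the second transcript-only gene (the
upstream-extension case) follows from the narrative, and is marked as such
in the fixture's note column. The catalogue's own arithmetic starts from
23 listed identifiers, of which 6 merge away and 2 are reclassified as
putative fragments; the summary reports what the table implies rather than
hard-coding any headline number.

## Known limitations

* Boundary pinning needs a junction peptide or transcript; exons supported
  only by interior peptides stay unresolved even when the protein evidence
  would suggest a boundary. This is deliberate (evidence ablation must
  never invent corrections) but conservative.
* Multi-locus (ambiguous) peptides are discarded as evidence; families
  with recently duplicated, near-identical members will under-merge.
* Non-canonical splice sites are out of scope; such cases are reported
  unresolvable.
* The aligner is a single fixed-scoring implementation; no E-values or
  significance estimates are attached, because the intended evidence is
  near-identity alignment, not sensitive homology search.
* Inversion repair trusts a single transcript chain; conflicting chains on
  one contig leave the anomaly unresolved rather than attempting a joint
  layout.
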