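gene_ids	location	transcript_id	protein_id	mass_da	figure	correction_class	evidence	status	note
RPRC015079	KQ035270:22283..29217	Rp-6850	R4G5J4	43622			protein	gene
RPRC015076	KQ035270:31145..38451	Rp-6846	T1IFK7/R4G5J6	43383/44846	Fig7	intron_retention	protein	gene	two proteoforms via intron retention
RPRC006028-RPRC006290	KQ034219:483622..531975	Rp-1760	R4G4V2	42388	Fig1	merge	protein	gene	novel intergenic exon; wrong-strand fragment re-stranded
RPRC006759	KQ034118:1424212..1434669	RP-3415	R4FJC3	45508	Fig3	terminal_exon_addition	protein	gene	novel terminal exon; ninth exon was a misclassified intron
RPRC004330-RPRC010954	KQ03421:413307..428406	RP-7417	R4FKP9	43820	Fig2	merge	protein	gene	exon fragment recovered on contig ACPB03042655
RPRC002478-RPRC002479	KQ035965:948..11511	Rp-10596	R4G3V2	44082	Fig5	merge	protein	gene	unannotated internal exon; C-terminal exon on contig KQ034470
RPRC014747-RPRC012504-RPRC008989	KQ037387:3342..4462-KQ036163:11128..17438	Rp-2814	R4FNG1	43137	Fig4	merge	protein	gene	three-way merge across two contigs
RPRC012508-RPRC012513	KQ036163:1315..9223	RP-8066	R4G4V0	43233	Fig6A	inversion_fix	transcript_only	gene	inverted block 3479-6718 re-oriented; transcript-validated
RPRC004171	KQ034610:35399..39782	RP-6421	R4G2R0	45341	Fig6B	upstream_exon_addition	transcript_only	gene	two upstream exons added; transcript-only support inferred from narrative
RPRC012785	KQ034079:4811..10271	Rp-2217	R4FNN7	44222			protein	gene
RPRC015082	KQ035270:12987..20613	RP-82226	R4FP52	43408			protein	gene
RPRC006698	KQ034534:71381..77412	RP-5007	R4FMP1	43907			protein	gene
RPRC012786	KQ034079:13511..18584		T1I914	42923			protein	gene
RPRC012664	KQ035425:10005..15720		T1I8P2	35511			none	gene	missing N-terminal
RPRC002696	KQ034126:569709..570120		T1HF74	11732			none	gene	truncated
RPRC011752	ACPB03043556:28..700		T1I633	15897			none	putative_fragment	cannot be regarded as an individual gene
RPRC012487	ACPB03042715:162..362		T1I865	7486			none	putative_fragment	cannot be regarded as an individual gene
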