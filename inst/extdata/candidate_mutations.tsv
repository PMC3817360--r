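# Prioritized candidate mutations in the evaluated QTL regions (galGal3).
# alt_reads: alternate-allele reads summed over both line pools; depth:
# total depth over both pools; qual: Phred-scaled site quality from the
# original pooled SNP calling (consumed as input); afd: estimated
# between-line allele frequency difference; pc/ec/pe: substitution scores
# (non-synonymous coding candidates only).
region	snp_bp	gene	snp_location	alt_reads	depth	qual	afd	pc	ec	pe
C1G1	174634021	ALG11	CpG island, upstream	7	10	72	0.97	N/A	N/A	N/A
C2G2	63823523	EDN1	CpG island, upstream	3	13	53	0.95	N/A	N/A	N/A
C3G4	33678270	CRIM1	Protein code, NS K/I	10	19	182	0.97	0.67	0.63	0.42
C4G6	12044024	VEGFR-2	CpG island, upstream	4	8	82	0.97	N/A	N/A	N/A
C4G6	12902414	FGF16	CpG island, downstream	8	16	175	0.95	N/A	N/A	N/A
C5G8	38316301	SNX6	CpG island, upstream	8	14	142	0.97	N/A	N/A	N/A
C7G9	21686625	GRB14	CpG island, downstream	3	12	52	0.97	N/A	N/A	N/A
C7G9	22711910	GCG	CpG island, downstream	3	9	46	0.87	N/A	N/A	N/A
C7G9	24802616	IGFBP2	Protein code, synonymous, CpG island	4	8	69	0.95	N/A	N/A	N/A
C20G12	8715398	BIRC7	Protein code, NS I/V	5	8	65	0.97	0.29	0.14	0.04
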