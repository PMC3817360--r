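# Candidate segments selected within the QTL regions by combined QTL and
# between-line divergence evidence; galGal3 coordinates in Mbp.
# qtl_support_mbp: size of the selected segment significant under the QTL
# model; n_genes: Ensembl genes in the initial list for the segment.
name	chrom	start_mbp	end_mbp	size_mbp	qtl_support_mbp	n_genes
C1G1	1	169.6	175.0	5.4	5.4	97
C2G2	2	59.7	65.4	5.7	2.1	52
C3G4	3	24.1	35.8	11.7	10.3	142
C4G6	4	10.6	12.9	2.3	0.0	62
C5G8	5	34.2	36.8	2.6	0.0	20
C5G8	5	38.2	39.0	0.8	0.0	16
C7G9	7	20.4	35.4	15.0	4.3	209
C20G12	20	8.3	9.5	1.2	1.2	38
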