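# Fine-mapped growth QTL regions, galGal3 (WUGSC 2.1) coordinates in Mbp.
# size_mbp is the originally reported size (report-level; reflects
# sub-0.1-Mbp coordinates), loaders recompute sizes from start/end.
name	qtl	chrom	start_mbp	end_mbp	size_mbp
C1G1	Growth1	1	169.6	181.0	11.4
C2G2	Growth2	2	47.9	65.4	17.5
C3G4	Growth4	3	24.0	68.0	43.9
C4G6	Growth6	4	1.3	13.5	12.1
C5G8	Growth8	5	33.6	39.0	5.3
C7G9	Growth9	7	10.9	35.4	24.5
C20G12	Growth12	20	7.1	13.8	6.7
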