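variant_id	gene_symbol	chrom	pos	ref	alt	region_classes	deep_intronic	uorf_high_impact	kozak_hit	polya_hit	ires_hit	mirna_hit	rbp_loss_hit	dorf_hit	tfbs_loss_hit	spliceai_max	cadd_phred	phylop	annotation_note
chr1_244051270_C_T	ZBTB18	chr1	244051269	C	T	promoter	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA	7.426	conserved promoter position 13 bp upstream of TSS
chr1_42958758_C_T	SLC2A1	chr1	42958757	C	T	five_utr	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA	NA	uAUG gained, out-of-frame oORF, strong Kozak (c.-107G>A)
chr2_189580685_A_C	SLC40A1	chr2	189580684	A	C	five_utr	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA	8.189	conserved 5'UTR position (c.-225T>G)
chr3_9397978_G_A	SETD5	chr3	9397977	G	A	five_utr_intron	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.97	NA	NA	5'UTR donor loss (c.-177+1G>A)
chr5_36953601_T_A	NIPBL	chr5	36953600	T	A	five_utr_intron	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.24	NA	NA	acceptor gain 17 bp upstream of final 5'UTR acceptor (c.-79-17T>A)
chr5_88823814_G_A	MEF2C	chr5	88823813	G	A	five_utr	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA	NA	uAUG gained, in-frame oORF (c.-26C>T)
chr11_31806844_C_T	PAX6	chr11	31806843	C	T	five_utr_intron	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.56	NA	NA	5'UTR donor loss (c.-52+5G>A)
chr11_31806926_CT_C	PAX6	chr11	31806925	CT	C	five_utr_intron	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.65	NA	NA	5'UTR acceptor loss (c.-128-2del)
chr11_119341418_C_A	MFRP	chr11	119341417	C	A	three_utr	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.56	NA	NA	3'UTR donor gain (c.*130G>T)
chr17_8382317_T_C	RPL26	chr17	8382316	T	C	five_utr_intron	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.97	35	NA	5'UTR acceptor loss (c.-5-2A>G)
chr20_58909654_A_G	GNAS	chr20	58909653	A	G	three_utr_intron	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.67	NA	NA	deep 3'UTR-intron acceptor gain (c.*625-30A>G)
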