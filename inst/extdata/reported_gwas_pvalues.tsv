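snp_id	closest_genes	chrom	pos	p_value
rs117503120	GBE1/LINC02027	3	81352557	6.45e-9
rs4483616	TENM4	11	78824323	8.84e-9
rs5998634	TIMP3/SYN3	22	33169115	8.06e-8
rs16866133	RBM45/OSBPL6	2	179022610	9.39e-8
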