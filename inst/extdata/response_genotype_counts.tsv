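snp_id	closest_genes	risk_allele	group	n0	n1	n2	chi2_printed	p_printed
rs117503120	GBE1/LINC02027	G	response	114	6	0	0.49	0.78
rs117503120	GBE1/LINC02027	G	nonresponse	62	1	0	0.49	0.78
rs5998634	TIMP3/SYN3	T	response	89	30	1	7.30	0.03
rs5998634	TIMP3/SYN3	T	nonresponse	59	4	0	7.30	0.03
rs16866133	RBM45/OSBPL6	T	response	119	4	0	0.04	0.98
rs16866133	RBM45/OSBPL6	T	nonresponse	63	0	0	0.04	0.98
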