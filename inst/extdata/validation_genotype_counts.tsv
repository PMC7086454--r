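snp_id	closest_genes	chrom	pos	risk_allele	group	n0	n1	n2	chi2_printed	or_printed	or_ci_printed	p_printed
rs117503120	GBE1/LINC02027	3	81352557	G	case	235	15	0	7.28	0.43	0.27-0.67	0.026
rs117503120	GBE1/LINC02027	3	81352557	G	control	215	35	0	7.28	0.43	0.27-0.67	0.026
rs5998634	TIMP3/SYN3	22	33169115	T	case	212	36	2	12.5	3.19	1.98-5.16	0.0019
rs5998634	TIMP3/SYN3	22	33169115	T	control	238	12	0	12.5	3.19	1.98-5.16	0.0019
rs16866133	RBM45/OSBPL6	2	179022610	T	case	247	3	0	7.73	0.20	0.08-0.49	0.03
rs16866133	RBM45/OSBPL6	2	179022610	T	control	235	15	0	7.73	0.20	0.08-0.49	0.03
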