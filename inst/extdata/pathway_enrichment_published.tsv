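pathway_name	total	observed	e_ratio	p_raw	adj_p
JAK-STAT signaling pathway	155	6	6.27	0.0004	0.0054
Neuroactive ligand-receptor interaction	256	8	5.06	0.0002	0.0054
Pathways in cancer	330	8	3.93	0.0011	0.0099
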