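chr2	178990000	179010000	RBM45	0	+
chr2	179030000	179110000	OSBPL6	0	-
chr3	81200000	81340000	GBE1	0	+
chr3	81360000	81420000	LINC02027	0	+
chr11	78700000	79000000	TENM4	0	-
chr22	33000000	33200000	SYN3	0	+
chr22	33180000	33260000	TIMP3	0	-
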