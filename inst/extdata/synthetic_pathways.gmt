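JAK-STAT-like signaling	synthetic set	TIMP3	SYN3	TENM4	GENEA1	GENEA2	GENEA3
Carbohydrate metabolism	synthetic set	GBE1	GENEB1	GENEB2	GENEB3	GENEB4
Lipid transport	synthetic set	OSBPL6	GENEC1	GENEC2
RNA processing	synthetic set	RBM45	GENED1	GENED2	GENED3	GENED4	GENED5	GENED6
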