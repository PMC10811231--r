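combination_index	status	detail	IFNG	LPS	GF	IL10	IFNGR	TLR4	JAK1	JAK2	STAT1	NFkB	ERK	IL10R	STAT3	TNF	Proliferation_M1_macrophage	Apoptosis_M1_macrophage	Inflammation_signal
0	stable	steady	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0
1	stable	steady	0	0	1	0	0	0	0	0	0	0	1	0	0	0	0	1	0
2	stable	steady	1	0	0	0	1	0	1	1	1	1	0	0	0	1	0	0	1
3	stable	steady	1	0	1	0	1	0	1	1	1	1	1	0	0	1	1	0	1
4	stable	steady	0	0	0	1	0	0	0	0	0	0	0	1	1	0	0	1	0
5	stable	steady	0	0	1	1	0	0	0	0	0	0	1	1	1	0	0	1	0
6	stable	steady	1	0	0	1	1	0	1	1	1	1	0	1	1	1	0	0	1
7	stable	steady	1	0	1	1	1	0	1	1	1	1	1	1	1	1	0	0	1
8	stable	steady	0	1	0	0	0	1	0	0	0	1	0	0	0	1	0	0	1
9	stable	steady	0	1	1	0	0	1	0	0	0	1	1	0	0	1	1	0	1
10	stable	steady	1	1	0	0	1	1	1	1	1	1	0	0	0	1	0	0	1
11	stable	steady	1	1	1	0	1	1	1	1	1	1	1	0	0	1	1	0	1
12	stable	steady	0	1	0	1	0	1	0	0	0	1	0	1	1	1	0	0	1
13	stable	steady	0	1	1	1	0	1	0	0	0	1	1	1	1	1	0	0	1
14	stable	steady	1	1	0	1	1	1	1	1	1	1	0	1	1	1	0	0	1
15	stable	steady	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1
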