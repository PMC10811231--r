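gene	logFC	adjP
TNF	2.1	0.001
STAT1	1.5	0.01
STAT3	-1.1	0.03
CASP7	0.9	0.04
IL6	3	0.2
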