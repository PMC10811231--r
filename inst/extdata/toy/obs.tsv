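node	value	provenance
IFNGR	1	expression
STAT1	1	expression
NFkB	1	literature
ERK	1	expression
STAT3	0	expression
TNF	1	both
Proliferation_M1_macrophage	1	literature
Apoptosis_M1_macrophage	0	literature
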