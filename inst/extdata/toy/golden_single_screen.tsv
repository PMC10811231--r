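target	status	Proliferation_M1_macrophage	Apoptosis_M1_macrophage	Inflammation_signal
NFkB	steady	suppressed	induced	suppressed
ERK	steady	suppressed	unchanged	unchanged
JAK1	steady	unchanged	unchanged	unchanged
JAK2	steady	unchanged	unchanged	unchanged
STAT3	steady	unchanged	unchanged	unchanged
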