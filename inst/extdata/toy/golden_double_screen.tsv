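target	status	Proliferation_M1_macrophage	Apoptosis_M1_macrophage	Inflammation_signal	synergy
NFkB+ERK	steady	suppressed	induced	suppressed	FALSE
NFkB+JAK1	steady	suppressed	induced	suppressed	FALSE
NFkB+JAK2	steady	suppressed	induced	suppressed	FALSE
NFkB+STAT3	steady	suppressed	induced	suppressed	FALSE
ERK+JAK1	steady	suppressed	unchanged	unchanged	FALSE
ERK+JAK2	steady	suppressed	unchanged	unchanged	FALSE
ERK+STAT3	steady	suppressed	unchanged	unchanged	FALSE
JAK1+JAK2	steady	suppressed	induced	suppressed	TRUE
JAK1+STAT3	steady	unchanged	unchanged	unchanged	FALSE
JAK2+STAT3	steady	unchanged	unchanged	unchanged	FALSE
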