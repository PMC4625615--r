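source	target	directed	sign	subtype
MAPK1	JUN	1	1	activation
MAPK1	FOS	1	1	activation
DUSP1	MAPK1	1	-1	dephosphorylation
JUN	FOS	0	0	binding
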