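line	CNF	DL	DN	FL	FZ	SB	TN
CNF	0.170	-0.072	0.044	0.008	-0.092	-0.091	0.013
DL	-0.072	0.143	-0.070	-0.072	0.025	0.048	-0.019
DN	0.044	-0.070	0.249	-0.018	-0.109	-0.105	-0.033
FL	0.008	-0.072	-0.018	0.158	-0.074	-0.087	0.010
FZ	-0.092	0.025	-0.109	-0.074	0.186	0.025	-0.034
SB	-0.091	0.048	-0.105	-0.087	0.025	0.121	0.039
TN	0.013	-0.019	-0.033	0.010	-0.034	0.039	0.051
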