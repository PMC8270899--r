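>CYTTTTTTCY	PRTE-synthetic-fixture	0
0.050	0.450	0.050	0.450
0.050	0.450	0.050	0.450
0.050	0.250	0.050	0.650
0.050	0.250	0.050	0.650
0.050	0.250	0.050	0.650
0.000	0.000	0.000	1.000
0.050	0.250	0.050	0.650
0.050	0.250	0.050	0.650
0.050	0.450	0.050	0.450
0.050	0.450	0.050	0.450
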