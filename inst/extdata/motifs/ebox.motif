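>CACGTG	Ebox-CACGTG	0
0.000	1.000	0.000	0.000
1.000	0.000	0.000	0.000
0.000	1.000	0.000	0.000
0.000	0.000	1.000	0.000
0.000	0.000	0.000	1.000
0.000	0.000	1.000	0.000
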