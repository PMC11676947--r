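key	value
P0	-47.31
P1	1.68
P2	0.97
P3	-3.46
P4	0.47
P5	-1.68
P6	-6.46
P7	3.43
P8	-1.14
P9	0.19
muV0	-60
dmuV0	10
sigmaV0	4
dsigmaV0	6
tauVN0	0.5
dtauVN0	1
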