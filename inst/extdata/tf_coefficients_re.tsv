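key	value
P0	-40.77
P1	-1.98
P2	-3.12
P3	3.57
P4	1.39
P5	-0.38
P6	-0.33
P7	0.16
P8	0.26
P9	-0.53
muV0	-60
dmuV0	10
sigmaV0	4
dsigmaV0	6
tauVN0	0.5
dtauVN0	1
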