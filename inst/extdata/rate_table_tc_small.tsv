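nu_e	nu_i	nu_out	sd_out	reps	se_out
0.1	0	0	0	2	0
0.1	10	0	0	2	0
0.1	40	0	0	2	0
0.296193629594517	0	0	0	2	0
0.296193629594517	10	0	0	2	0
0.296193629594517	40	0	0	2	0
0.877306662123742	0	1.75	0.353553390593274	2	0.25
0.877306662123742	10	0	0	2	0
0.877306662123742	40	0	0	2	0
2.59852644521882	0	40.5	0.707106781186548	2	0.5
2.59852644521882	10	4.75	1.06066017177982	2	0.75
2.59852644521882	40	0	0	2	0
7.69666979406701	0	97.5	0	2	0
7.69666979406701	10	69.5	0.707106781186548	2	0.5
7.69666979406701	40	2.5	2.12132034355964	2	1.5
22.7970456209519	0	143	0	2	0
22.7970456209519	10	137	0.707106781186548	2	0.5
22.7970456209519	40	98.5	0.707106781186548	2	0.5
67.5233968650155	0	170	0	2	0
67.5233968650155	10	168.75	0.353553390593274	2	0.25
67.5233968650155	40	164.5	0	2	0
200	0	185	0	2	0
200	10	184.75	0.353553390593274	2	0.25
200	40	183	0	2	0
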