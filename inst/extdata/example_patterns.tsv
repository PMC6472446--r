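n1	r1	n2	r2	weight
10	0	10	0	189
10	4	10	0	1
10	10	10	0	1
10	0	10	1	2
10	4	10	1	1
10	0	10	3	1
10	5	10	3	1
10	10	10	6	1
10	10	10	9	2
10	1	10	10	1
10	6	10	10	1
10	9	10	10	1
10	10	10	10	198
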