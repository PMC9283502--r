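year	location	group	n	LL	LF	FF	MM	MI	II
2019	Boone-IA	pre	120	51	69	0	92	28	0
2019	Boone-IA	post	47	4	35	8	31	16	0
2019	Kanawha-IA	pre	120	0	102	18	113	7	0
2019	Kanawha-IA	post	103	1	79	23	71	32	0
2019	Sutherland-IA	pre	115	25	90	0	81	34	0
2019	Sutherland-IA	post	95	0	95	0	66	29	0
2020	Nashua-IA	pre	110	61	47	2	98	12	0
2020	Nashua-IA	post	38	0	38	0	0	38	0
2020	Sutherland-IA	pre	110	14	10	86	95	15	0
2020	Sutherland-IA	post	95	1	40	54	85	10	0
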