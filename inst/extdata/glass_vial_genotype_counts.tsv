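year	insecticide	location	group	n	LL_MM	LL_MI	LL_II	LF_MM	LF_MI	LF_II	FF_MM	FF_MI	FF_II
2019	bifenthrin	Boone-IA	moribund	32	2	10	0	19	1	0	0	0	0
2019	bifenthrin	Boone-IA	survivor	8	1	2	0	5	0	0	0	0	0
2019	bifenthrin	Kanawha-IA	moribund	29	0	0	0	28	0	0	1	0	0
2019	bifenthrin	Kanawha-IA	survivor	11	0	0	0	8	1	0	2	0	0
2019	bifenthrin	Sutherland-IA	moribund	37	5	1	0	27	4	0	0	0	0
2019	bifenthrin	Sutherland-IA	survivor	2	0	0	0	0	2	0	0	0	0
2019	bifenthrin	Darwin-MN	moribund	20	4	3	0	7	3	0	3	0	0
2019	bifenthrin	Darwin-MN	survivor	17	0	1	0	9	6	0	1	0	0
2019	bifenthrin	All locations	moribund	118	11	14	0	81	8	0	4	0	0
2019	bifenthrin	All locations	survivor	38	1	3	0	22	9	0	3	0	0
2019	lambda-cyhalothrin	Boone-IA	moribund	40	12	3	0	23	2	0	0	0	0
2019	lambda-cyhalothrin	Boone-IA	survivor	0	0	0	0	0	0	0	0	0	0
2019	lambda-cyhalothrin	Kanawha-IA	moribund	35	0	0	0	34	0	0	1	0	0
2019	lambda-cyhalothrin	Kanawha-IA	survivor	5	0	0	0	1	2	0	2	0	0
2019	lambda-cyhalothrin	Sutherland-IA	moribund	15	5	1	0	5	4	0	0	0	0
2019	lambda-cyhalothrin	Sutherland-IA	survivor	22	3	2	0	8	9	0	0	0	0
2019	lambda-cyhalothrin	Darwin-MN	moribund	20	4	6	0	8	1	0	1	0	0
2019	lambda-cyhalothrin	Darwin-MN	survivor	20	1	5	0	5	9	0	0	0	0
2019	lambda-cyhalothrin	All locations	moribund	110	21	10	0	70	7	0	2	0	0
2019	lambda-cyhalothrin	All locations	survivor	47	4	7	0	14	20	0	2	0	0
2020	bifenthrin	Nashua-IA	moribund	38	27	0	0	9	2	0	0	0	0
2020	bifenthrin	Nashua-IA	survivor	0	0	0	0	0	0	0	0	0	0
2020	bifenthrin	Sutherland-IA	moribund	20	0	0	0	0	0	0	20	0	0
2020	bifenthrin	Sutherland-IA	survivor	18	0	1	0	0	0	0	17	0	0
2020	bifenthrin	All locations	moribund	58	27	0	0	9	2	0	20	0	0
2020	bifenthrin	All locations	survivor	18	0	1	0	0	0	0	17	0	0
2020	lambda-cyhalothrin	Nashua-IA	moribund	29	17	1	0	10	1	0	0	0	0
2020	lambda-cyhalothrin	Nashua-IA	survivor	8	3	0	0	4	0	0	1	0	0
2020	lambda-cyhalothrin	Sutherland-IA	moribund	33	1	0	0	3	0	0	29	0	0
2020	lambda-cyhalothrin	Sutherland-IA	survivor	3	0	0	0	0	0	0	3	0	0
2020	lambda-cyhalothrin	All locations	moribund	62	18	1	0	13	1	0	29	0	0
2020	lambda-cyhalothrin	All locations	survivor	11	3	0	0	4	0	0	4	0	0
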