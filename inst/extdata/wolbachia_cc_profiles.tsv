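st_id	wsp	ftsZ	groEL	trmD	frequency	complex	is_founder	host
4	1	2	8	1	2	I	TRUE	BK-B
9	1	2	8	3	1	I	FALSE	BK-B
5	1	2	8	10	1	I	FALSE	BK-B
2	1	2	4	1	12	I	FALSE	BK-B
1	1	1	4	1	1	I	FALSE	BK-B
11	1	2	8	6	1	I	FALSE	BK-D
6	5	2	8	6	1	I	FALSE	BK-D
30	12	10	8	1	1	II	TRUE	BK-B
29	12	10	8	14	1	II	FALSE	BspI
28	12	10	8	6	1	II	FALSE	BK-D
27	12	10	8	2	1	II	FALSE	BK-B
16	5	3	8	1	2	III	TRUE	BK-D
15	3	3	8	1	1	III	FALSE	BK-D
14	5	3	4	1	1	III	FALSE	BK-D
13	5	3	8	5	1	III	FALSE	BR
36	12	10	12	17	1	IV	FALSE	BR
10	12	10	12	15	1	IV	FALSE	BspI
12	4	10	12	15	1	IV	FALSE	BR
24	12	10	12	8	3	IV	TRUE	BK-D
25	12	10	11	8	1	IV	FALSE	BK-D
33	6	14	3	9	8	V	TRUE	BS
34	6	14	3	11	1	V	FALSE	BS
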