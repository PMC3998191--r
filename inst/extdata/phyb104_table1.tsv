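stagger	designed	detected	percent
2	77	66	86
6	25	22	88
10	15	14	93
12	12	12	100
15	10	9	90
17	9	8	89
20	8	7	88
22	7	7	100
25	6	6	100
27	5	5	100
30	5	4	80
32	5	5	100
35	5	5	100
37	4	4	100
40	4	4	100
42	4	3	75
45	3	3	100
47	3	3	100
49	3	3	100
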