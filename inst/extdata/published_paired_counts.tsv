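pair	exposed_events	printed_pct_exposed	unexposed_events	printed_pct_unexposed
1	138	9.24	14	1.31
2	89	5.96	6	0.56
3	109	7.30	14	1.31
4	109	7.30	7	0.65
5	65	4.35	21	1.97
6	60	4.01	4	0.37
7	105	7.03	10	0.94
8	43	2.88	14	1.31
9	4	0.26	2	0.18
10	5	0.33	6	0.56
11	3	0.20	5	0.47
12	54	3.61	28	2.63
13	62	4.15	10	0.94
14	5	0.33	8	0.75
15	15	1.00	8	0.75
16	0	0	5	0.47
17	42	2.81	8	0.75
18	101	6.76	5	0.47
19	52	3.48	4	0.37
20	45	3.01	0	0
21	31	2.07	1	0.09
22	43	2.88	10	0.94
23	14	0.93	0	0
24	28	1.87	7	0.65
25	30	2.00	2	0.18
26	23	1.54	1	0.09
27	72	4.82	0	0
28	13	0.87	2	0.18
29	26	1.74	1	0.09
30	16	1.07	2	0.18
31	6	0.40	0	0
32	12	0.80	2	0.18
33	16	1.07	1	0.09
34	35	2.34	1	0.09
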