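trial	block	cue	role	original_role	us	onset_s
1	1	A	CS+	CS+	0	0
2	1	A	CS+	CS+	0	16
3	1	B	CS-	CS-	0	32
4	1	A	CS+	CS+	0	48
5	1	A	CS+	CS+	1	64
6	1	B	CS-	CS-	0	80
7	1	A	CS+	CS+	0	96
8	1	B	CS-	CS-	0	112
9	1	B	CS-	CS-	0	128
10	1	A	CS+	CS+	1	144
11	1	A	CS+	CS+	0	160
12	1	B	CS-	CS-	0	176
13	1	A	CS+	CS+	0	192
14	1	A	CS+	CS+	1	208
15	1	B	CS-	CS-	0	224
16	1	A	CS+	CS+	0	240
17	1	B	CS-	CS-	0	256
18	1	B	CS-	CS-	0	272
19	1	A	CS+	CS+	1	288
20	1	A	CS+	CS+	0	304
21	2	B	CS+	CS-	0	330
22	2	B	CS+	CS-	0	346
23	2	A	CS-	CS+	0	362
24	2	A	CS-	CS+	0	378
25	2	B	CS+	CS-	0	394
26	2	B	CS+	CS-	0	410
27	2	A	CS-	CS+	0	426
28	2	B	CS+	CS-	1	442
29	2	A	CS-	CS+	0	458
30	2	B	CS+	CS-	1	474
31	2	A	CS-	CS+	0	490
32	2	B	CS+	CS-	1	506
33	2	B	CS+	CS-	0	522
34	2	A	CS-	CS+	0	538
35	2	B	CS+	CS-	0	554
36	2	B	CS+	CS-	0	570
37	2	A	CS-	CS+	0	586
38	2	A	CS-	CS+	0	602
39	2	B	CS+	CS-	0	618
40	2	B	CS+	CS-	1	634
41	3	A	CS+	CS+	0	660
42	3	B	CS-	CS-	0	676
43	3	A	CS+	CS+	0	692
44	3	A	CS+	CS+	0	708
45	3	B	CS-	CS-	0	724
46	3	A	CS+	CS+	1	740
47	3	A	CS+	CS+	0	756
48	3	B	CS-	CS-	0	772
49	3	A	CS+	CS+	0	788
50	3	B	CS-	CS-	0	804
51	3	B	CS-	CS-	0	820
52	3	A	CS+	CS+	1	836
53	3	B	CS-	CS-	0	852
54	3	A	CS+	CS+	1	868
55	3	A	CS+	CS+	0	884
56	3	B	CS-	CS-	0	900
57	3	A	CS+	CS+	0	916
58	3	A	CS+	CS+	0	932
59	3	B	CS-	CS-	0	948
60	3	A	CS+	CS+	1	964
61	4	B	CS+	CS-	0	990
62	4	A	CS-	CS+	0	1006
63	4	B	CS+	CS-	0	1022
64	4	B	CS+	CS-	0	1038
65	4	A	CS-	CS+	0	1054
66	4	B	CS+	CS-	0	1070
67	4	B	CS+	CS-	1	1086
68	4	A	CS-	CS+	0	1102
69	4	B	CS+	CS-	1	1118
70	4	B	CS+	CS-	0	1134
71	4	A	CS-	CS+	0	1150
72	4	B	CS+	CS-	0	1166
73	4	B	CS+	CS-	0	1182
74	4	A	CS-	CS+	0	1198
75	4	A	CS-	CS+	0	1214
76	4	B	CS+	CS-	1	1230
77	4	A	CS-	CS+	0	1246
78	4	A	CS-	CS+	0	1262
79	4	B	CS+	CS-	0	1278
80	4	B	CS+	CS-	1	1294
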