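# Synthetic per-position secondary-structure profile (toy self-complementarity
# score from toy_structure_profile(); NOT a thermodynamic ensemble prediction).
# Template: swapped extension region, positions in extension order.
position	s
1	1
2	0.75
3	0.8
4	0.8
5	0.6
6	0.6
7	0.8
8	0.6
9	0.6
10	0.6
11	0.8
12	0.6
13	0.6
14	0.6667
15	0.6
16	0.6667
17	0.6
18	0.6
19	0.8
20	0.6
21	0.8
22	0.8
23	0.8
24	0.6
25	0.8
26	0.6
27	0.6667
28	0.8
29	0.8
30	0.8
31	1
32	0.6
33	0.6
34	0.8
35	0.8
36	0.8
37	0.6
38	0.6667
39	0.4
40	0.4
41	0.4
42	0.4
43	0.4
44	0.6
45	0.6
46	0.6
47	0.6
48	0.6667
49	0.4
50	0.6
51	0.8
52	0.8
53	0.8
54	0.8
55	0.8
56	0.8
57	0.8
58	0.8
59	0.8
60	0.8
61	0.8
62	0.8
63	0.8
64	0.8
65	0.75
66	0.6667
67	0.6
68	0.8
69	0.6
70	0.6
71	0.6667
72	0.6
73	0.6
74	0.6
75	0.75
76	0.6667
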