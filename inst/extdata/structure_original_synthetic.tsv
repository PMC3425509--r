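# Synthetic per-position secondary-structure profile (toy self-complementarity
# score from toy_structure_profile(); NOT a thermodynamic ensemble prediction).
# Template: original extension region, positions in extension order.
position	s
1	0.3333
2	0.5
3	0.4
4	0.6
5	0.6
6	0.6
7	0.6
8	0.6
9	0.4
10	0.6
11	0.8
12	0.8
13	0.8
14	0.8
15	0.8
16	0.8
17	0.8
18	0.8
19	0.8
20	0.8
21	0.8
22	0.8
23	0.8
24	0.8
25	0.6
26	0.6
27	0.6
28	0.8
29	0.6
30	0.6
31	0.6
32	0.6
33	0.6
34	0.6
35	0.6
36	0.6
37	0.6
38	0.8
39	0.8
40	0.8
41	0.6
42	0.6
43	0.8
44	0.6
45	0.6
46	0.6
47	0.8
48	0.6
49	0.6
50	0.6
51	0.6
52	0.6
53	0.6
54	0.6
55	0.8
56	0.6
57	0.8
58	0.8
59	0.8
60	0.6
61	0.8
62	0.6
63	0.6
64	0.8
65	0.8
66	0.8
67	0.8
68	0.6
69	0.6
70	0.8
71	0.8
72	0.8
73	0.6
74	0.4
75	0.5
76	0.3333
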