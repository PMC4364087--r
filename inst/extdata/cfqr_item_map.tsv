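item	domain	reverse	subquestion
1	physical	0	0
2	physical	0	0
3	physical	1	0
4	physical	0	0
5	physical	0	0
6	physical	0	0
7	physical	1	0
8	physical	0	0
9	role	0	0
10	role	0	0
11	role	0	0
12	role	0	0
13	vitality	0	0
14	vitality	0	0
15	vitality	1	0
16	vitality	0	0
17	emotion	0	0
18	emotion	1	0
19	emotion	0	0
20	emotion	1	0
21	emotion	0	0
22	social	0	0
23	social	0	0
24	social	1	0
25	social	0	0
26	social	0	0
27	social	0	0
28	body_image	1	0
29	body_image	1	0
30	body_image	1	0
31	eat	1	0
32	eat	1	0
33	eat	1	0
34	treatment	1	0
35	treatment	1	0
36	treatment	1	0
37	health	1	0
38	health	1	0
39	health	1	0
40	weight	1	0
41	respiratory	1	0
42	respiratory	1	0
43	respiratory	1	1
44	respiratory	1	0
45	respiratory	1	0
46	respiratory	1	0
47	respiratory	1	0
48	digest	1	0
49	digest	1	0
50	digest	1	0
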