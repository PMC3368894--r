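	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23	24	25	26	27	28	29	30	31
1	0	0	0	-0.5	0	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	-0.5
2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
4	-0.5	0	0	0	0	0	0	0	0	-0.5	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	-0.5	0	0	-0.5	0	-0.5
5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
6	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
7	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
8	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
9	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
10	-0.5	0	0	-0.5	0	0	0	0	0	-0.5	-0.5	-0.5	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	-0.5	0	0	-0.5	0	-0.5
11	-0.5	0	0	0	0	0	0	0	0	-0.5	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	-0.5	0	0	-0.5	0	-0.5
12	-0.5	0	0	0	0	0	0	0	0	-0.5	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	-0.5	0	0	-0.5	0	-0.5
13	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
14	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
15	0	0	0	-0.5	0	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	-0.5
16	0	0	0	-0.5	0	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	-0.5
17	0	0	0	-0.5	0	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	-0.5
18	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
19	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
20	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
21	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
22	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
23	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
24	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
25	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
26	0	0	0	-0.5	0	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	-0.5
27	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
28	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
29	0	0	0	-0.5	0	0	0	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	-0.5
30	0	0	0	0	0	-0.5	-0.5	-0.5	-0.5	0	0	0	0	-0.5	0	0	0	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	0	-0.5	-0.5	0	-0.5	0
31	-0.5	0	0	-0.5	0	0	0	0	0	-0.5	-0.5	-0.5	0	0	-0.5	-0.5	-0.5	0	0	0	0	0	0	0	0	-0.5	0	0	-0.5	0	0
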