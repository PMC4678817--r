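position	A	C	G	T
1	0.10	0.31	0.11	0.48
2	0.10	0.31	0.11	0.48
3	0.10	0.31	0.11	0.48
4	0.10	0.31	0.11	0.48
5	0.10	0.31	0.11	0.48
6	0.10	0.31	0.11	0.48
7	0.10	0.31	0.11	0.48
8	0.10	0.31	0.11	0.48
9	0.10	0.31	0.11	0.48
10	0.10	0.31	0.11	0.48
11	0.10	0.31	0.11	0.48
12	0.10	0.31	0.11	0.48
13	0.10	0.31	0.11	0.48
14	0.10	0.31	0.11	0.48
15	0.12	0.30	0.10	0.48
16	0.08	0.33	0.07	0.52
17	0.22	0.30	0.10	0.38
18	0.05	0.62	0.02	0.31
19	0.25	0.14	0.50	0.11
20	0.25	0.22	0.25	0.28
21	0.22	0.26	0.24	0.28
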