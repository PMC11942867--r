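1	0	8e+06	p36	gneg
1	8e+06	1.6e+07	p22	gpos50
1	1.6e+07	2e+07	p13.3	gneg
1	2e+07	2.4e+07	p11	gpos50
1	2.4e+07	3e+07	q11	gneg
1	3e+07	4e+07	q23.1	gpos50
1	4e+07	6e+07	q32	gneg
2	0	1e+07	p25	gneg
2	1e+07	2.2e+07	p11	gpos50
2	2.2e+07	2.8e+07	q11	gneg
2	2.8e+07	3.6e+07	q14.2	gpos50
2	3.6e+07	5.5e+07	q37	gneg
3	0	8e+06	p26	gneg
3	8e+06	1.6e+07	p12.1	gpos50
3	1.6e+07	2e+07	p11	gneg
3	2e+07	2.6e+07	q11	gpos50
3	2.6e+07	5e+07	q26	gneg
5	0	1e+07	p15	gneg
5	1e+07	2e+07	p11	gpos50
5	2e+07	2.8e+07	q11	gneg
5	2.8e+07	3.6e+07	q31.2	gpos50
5	3.6e+07	5e+07	q35	gneg
6	0	6e+06	p25	gneg
6	6e+06	1e+07	p21.32	gpos50
6	1e+07	1.4e+07	p21.31	gneg
6	1.4e+07	1.7e+07	p21.1	gpos50
6	1.7e+07	1.8e+07	p11	gneg
6	1.8e+07	2.4e+07	q11	gpos50
6	2.4e+07	4.5e+07	q25	gneg
9	0	6e+06	p24	gneg
9	6e+06	1.2e+07	p21.3	gpos50
9	1.2e+07	1.6e+07	p11	gneg
9	1.6e+07	2.2e+07	q11	gpos50
9	2.2e+07	4e+07	q34	gneg
10	0	9e+06	p15	gneg
10	9e+06	1.8e+07	p11	gpos50
10	1.8e+07	2.4e+07	q11	gneg
10	2.4e+07	3.2e+07	q24	gpos50
10	3.2e+07	4.5e+07	q26	gneg
11	0	8e+06	p15	gneg
11	8e+06	1.6e+07	p11	gpos50
11	1.6e+07	2.2e+07	q11	gneg
11	2.2e+07	4e+07	q24.3	gpos50
12	0	1.2e+07	p13	gneg
12	1.2e+07	2.4e+07	p11	gpos50
12	2.4e+07	2.6e+07	q11	gneg
12	2.6e+07	3e+07	q13.3	gpos50
12	3e+07	3.3e+07	q14.1	gneg
12	3.3e+07	3.6e+07	q14.3	gpos50
12	3.6e+07	4e+07	q15	gneg
12	4e+07	5e+07	q21	gpos50
12	5e+07	6e+07	q24	gneg
13	0	5e+06	p11	gneg
13	5e+06	1e+07	q11	gpos50
13	1e+07	1.8e+07	q14.2	gneg
13	1.8e+07	3.5e+07	q34	gpos50
16	0	6e+06	p13	gneg
16	6e+06	1e+07	p11.2	gpos50
16	1e+07	1.2e+07	p11	gneg
16	1.2e+07	1.8e+07	q11	gpos50
16	1.8e+07	3e+07	q24	gneg
17	0	5e+06	p13.2	gneg
17	5e+06	9e+06	p13.1	gpos50
17	9e+06	1.2e+07	p11	gneg
17	1.2e+07	1.8e+07	q11	gpos50
17	1.8e+07	3e+07	q25	gneg
18	0	6e+06	p11	gneg
18	6e+06	1.4e+07	q11.2	gpos50
18	1.4e+07	3e+07	q23	gneg
21	0	5e+06	p11	gneg
21	5e+06	1e+07	q11	gpos50
21	1e+07	1.6e+07	q22.2	gneg
21	1.6e+07	2.5e+07	q22.3	gpos50
22	0	5e+06	p11	gneg
22	5e+06	9e+06	q11	gpos50
22	9e+06	1.4e+07	q12.1	gneg
22	1.4e+07	1.8e+07	q12.2	gpos50
22	1.8e+07	2.5e+07	q13	gneg
X	0	8e+06	p22	gneg
X	8e+06	1.4e+07	p11.23	gpos50
X	1.4e+07	1.6e+07	p11	gneg
X	1.6e+07	2.2e+07	q11	gpos50
X	2.2e+07	4e+07	q28	gneg
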