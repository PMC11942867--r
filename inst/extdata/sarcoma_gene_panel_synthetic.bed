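1	10000000	10200000	TGFBR3	0	-	fusion_partner	p22
1	17000000	17050000	CSF1	0	+	fusion_partner	p13.3
1	34000000	34050000	NTRK1	0	+	oncogene	q23.1
2	30000000	30200000	GLI2	0	+	oncogene	q14.2
2	50000000	50100000	COL6A3	0	-	fusion_partner	q37
3	12000000	12100000	VGLL3	0	+	oncogene	p12.1
5	31000000	31050000	CXXC5	0	+	fusion_partner	q31.2
6	8000000	8050000	PHF1	0	+	fusion_partner	p21.32
6	11000000	11020000	SRSF3	0	+	fusion_partner	p21.31
6	15000000	15200000	RUNX2	0	+	oncogene	p21.1
9	8000000	8030000	CDKN2A	0	-	tumor_suppressor	p21.3
9	8100000	8130000	CDKN2B	0	-	tumor_suppressor	p21.3
10	27000000	27030000	OGA	0	-	fusion_partner	q24
11	30000000	30100000	FLI1	0	+	fusion_partner	q24.3
12	27000000	27050000	NAB2	0	+	fusion_partner	q13.3
12	27060000	27120000	STAT6	0	-	fusion_partner	q13.3
12	28500000	28520000	DDIT3	0	-	fusion_partner	q13.3
12	31000000	31050000	CDK4	0	-	oncogene	q14.1
12	34000000	34150000	HMGA2	0	+	oncogene	q14.3
12	37000000	37100000	MDM2	0	+	oncogene	q15
13	13000000	13200000	RB1	0	+	tumor_suppressor	q14.2
16	7000000	7050000	FUS	0	+	fusion_partner	p11.2
17	2000000	2100000	USP6	0	+	fusion_partner	p13.2
17	6000000	6030000	TP53	0	-	tumor_suppressor	p13.1
18	8000000	8100000	SS18	0	-	fusion_partner	q11.2
21	12000000	12300000	ERG	0	-	fusion_partner	q22.2
22	10000000	10050000	MN1	0	-	fusion_partner	q12.1
22	15000000	15100000	EWSR1	0	+	fusion_partner	q12.2
X	10000000	10020000	SSX1	0	-	fusion_partner	p11.23
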