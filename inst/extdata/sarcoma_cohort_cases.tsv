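case_id	diagnosis	expected_rule	category	detected	detection_tier	refined	total_dna_gbp	effective_coverage
3	G3 Undifferentiated Pleomorphic Sarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1513.96	366.74
5	G3 Myxofibrosarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1507.80	381.03
8	Myxoid Liposarcoma	fusion(FUS,DDIT3)	fusion	TRUE	RVA	FALSE	640.20	107.44
9	Dedifferentiated Parosteal Osteosarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1500.01	379.76
12	G3 Undifferentiated Pleomorphic Sarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1502.11	351.86
14	G1 Myxofibrosarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1518.97	294.82
19	Dedifferentiated Liposarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1188.88	154.24
20	Low-Grade Myofibroblastic Lesion	cnv_sv_any	fusion	TRUE	RVA	TRUE	1511.15	202.35
22	Well-Differentiated Liposarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1502.11	391.16
23	G3 Myxofibrosarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1516.40	366.11
24	Atypical Lipomatous Liposarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1544.76	399.65
25	Lipoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1513.80	388.96
26	G3 Undifferentiated Pleomorphic Sarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1508.79	408.45
28	Dedifferentiated Liposarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1501.12	394.68
29	G3 Myxofibrosarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1456.12	317.03
30	Ewing Sarcoma	cnv_sv_any	fusion	TRUE	RVA	TRUE	1545.00	417.77
31	Superficial CD34+ Fibroblastic Tumor	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1371.84	260.05
33	Malignant Tenosynovial Giant Cell Tumor	fusion(COL6A3,CSF1)	fusion	FALSE	NONE	FALSE	1511.78	415.80
34	Atypical Fibromyxoid Ossifying Tumor	gene_rearrangement(PHF1)	fusion	TRUE	RVA	FALSE	1514.63	377.71
35	Dedifferentiated Liposarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1514.09	339.48
36	Solitary Fibrous Tumor	fusion(NAB2,STAT6)	fusion	TRUE	DENOVO	FALSE	1522.03	402.56
39	Dedifferentiated Liposarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1548.60	413.73
40	G3 Myxofibrosarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1506.95	202.71
41	G3 Myxofibrosarcoma	cnv_sv_any	fusion	TRUE	RVA	TRUE	1501.94	379.13
42	Monophasic Synovial Sarcoma	fusion(SS18,SSX1)	fusion	TRUE	RVA	FALSE	1518.48	344.09
43	G3 Osteosarcoma NOS	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1507.71	310.69
44	Ewing Sarcoma	fusion(FUS,ERG)	fusion	TRUE	RVA	FALSE	724.03	122.79
46	High Grade Myxoid Liposarcoma	fusion(FUS,DDIT3)	fusion	TRUE	RVA	FALSE	1453.70	415.64
47	G1 Myxofibrosarcoma	cnv_sv_any	cnv_sv	TRUE	RVA	FALSE	1501.50	365.60
48	Ewing Sarcoma	fusion(EWSR1,FLI1)	fusion	TRUE	RVA	FALSE	1502.46	394.20
49	Dedifferentiated Liposarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1515.32	358.94
50	Myxoid Liposarcoma	fusion(FUS,DDIT3)	fusion	TRUE	RVA	FALSE	1516.61	364.82
51	Dedifferentiated Liposarcoma	amplification(MDM2)	mdm2_amplification	TRUE	RVA	FALSE	1501.60	185.60
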