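case_id	initial_diagnosis	revised_diagnosis	key_events	iscn
20	Low-Grade Myofibroblastic Lesion	Nodular Fasciitis	fusion(SRSF3,USP6)	t(6;17)(p21.31;p13.2)
30	Small Round Cell Sarcoma, Ewing-like	Small Round Cell Sarcoma, unclassified	fusion(MN1,CXXC5)	t(5;22)(q31.2;q12.1)
41	G3 Myxofibrosarcoma	Myxoinflammatory Fibroblastic Sarcoma	amplification(VGLL3);monosomy(13);fusion(OGA,TGFBR3)	t(1;10)(p22;q24)
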