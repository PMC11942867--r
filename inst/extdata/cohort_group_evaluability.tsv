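group	n_evaluable	n_total
adipocytic	12	21
non_adipocytic	11	15
bone	2	6
uncertain	5	7
srcs	3	4
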