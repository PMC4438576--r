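upn	ctnnb1_status	braf_status	age_at_dx
411	S33F	WT	2
463	S37F	WT	4
598	S37C	WT	18
646	D32N	WT	7
673	S37F	WT	2
740	S33F	WT	12
802	WT	WT	7
883	WT	WT	6
956	S37C	WT	9
980	D32N	WT	13
1000	S45F	WT	0
9109	WT	WT	9
9201	T41I	WT	-
9202	T41I	WT	-
9302	WT	WT	-
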