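strain	total	annotated	GT/AG	GC/AG	AT/AC	overlap_gene
129	51	8	47	4	0	32
AJ	53	6	45	7	1	40
B6	66	24	64	2	0	55
CAST	651	18	545	99	7	427
NOD	40	2	32	7	1	22
NZO	42	0	38	4	0	30
PWK	482	23	401	73	8	318
WSB	124	2	109	13	2	76
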