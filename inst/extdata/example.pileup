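locus	1	A	21	.....................	IIIIIIIIIIIIIIIIIIIII	22	......................	IIIIIIIIIIIIIIIIIIIIII	23	.......................	IIIIIIIIIIIIIIIIIIIIIII
locus	2	C	22	......................	IIIIIIIIIIIIIIIIIIIIII	24	........................	IIIIIIIIIIIIIIIIIIIIIIII	26	..........................	IIIIIIIIIIIIIIIIIIIIIIIIII
locus	3	G	39	.......................TTTTTTTTTTTTTTTT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	42	..........................TTTTTTTTTTTTTTTT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	38	......................TTTTTTTTTTTTTTTT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
locus	4	T	24	........................	IIIIIIIIIIIIIIIIIIIIIIII	21	.....................	IIIIIIIIIIIIIIIIIIIII	25	.........................	IIIIIIIIIIIIIIIIIIIIIIIII
locus	5	A	25	.........................	IIIIIIIIIIIIIIIIIIIIIIIII	23	.......................	IIIIIIIIIIIIIIIIIIIIIII	21	.....................	IIIIIIIIIIIIIIIIIIIII
locus	6	C	44	..........................AAAAAAAAAAAAAAAAAA	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	25	.........................	IIIIIIIIIIIIIIIIIIIIIIIII	41	........................AAAAAAAAAAAAAAAAA	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
locus	7	G	20	....................	IIIIIIIIIIIIIIIIIIII	20	....................	IIIIIIIIIIIIIIIIIIII	20	....................	IIIIIIIIIIIIIIIIIIII
locus	8	T	21	.....................	IIIIIIIIIIIIIIIIIIIII	22	......................	IIIIIIIIIIIIIIIIIIIIII	23	.......................	IIIIIIIIIIIIIIIIIIIIIII
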