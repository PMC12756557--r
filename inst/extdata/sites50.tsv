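chrom	pos	ref	alt
ctg1	1	A	C
ctg1	2	A	C
ctg1	3	A	C
ctg1	4	A	C
ctg1	5	A	C
ctg1	6	A	C
ctg1	7	A	C
ctg1	8	A	C
ctg1	9	A	C
ctg1	10	A	C
ctg1	11	A	C
ctg1	12	A	C
ctg1	13	A	C
ctg1	14	A	C
ctg1	15	A	C
ctg1	16	A	C
ctg1	17	A	C
ctg1	18	A	C
ctg1	19	A	C
ctg1	20	A	C
ctg1	21	A	C
ctg1	22	A	C
ctg1	23	A	C
ctg1	24	A	C
ctg1	25	A	C
ctg1	26	A	C
ctg1	27	A	C
ctg1	28	A	C
ctg1	29	A	C
ctg1	30	A	C
ctg1	31	A	C
ctg1	32	A	C
ctg1	33	A	C
ctg1	34	A	C
ctg1	35	A	C
ctg1	36	A	C
ctg1	37	A	C
ctg1	38	A	C
ctg1	39	A	C
ctg1	40	A	C
ctg1	41	A	C
ctg1	42	A	C
ctg1	43	A	C
ctg1	44	A	C
ctg1	45	A	C
ctg1	46	A	C
ctg1	47	A	C
ctg1	48	A	C
ctg1	49	A	C
ctg1	50	A	C
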