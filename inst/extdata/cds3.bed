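ctg1	4	10	cds_a
ctg1	14	25	cds_b
ctg1	39	43	cds_c
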