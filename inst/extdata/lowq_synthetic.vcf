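##fileformat=VCFv4.2
##source=vafclust synthetic low-quality fixture
##contig=<ID=ctg1>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">
##INFO=<ID=AO,Number=A,Type=Integer,Description="Alternate allele observation count">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
ctg1	100	.	A	G	60	.	DP=20;AO=8
ctg1	200	.	C	T	30	.	DP=30;AO=12
ctg1	300	.	G	A	25	.	DP=10;AO=4
ctg1	400	.	T	C	50.5	.	DP=40;AO=19
ctg1	500	.	A	C	12	.	DP=15;AO=5
ctg1	600	.	A	G,T	45	.	DP=30;AO=5,3
ctg1	700	.	C	G	8	.	DP=25;AO=6
ctg1	800	.	G	C	33	.	DP=21;AO=4
ctg1	900	.	T	A	70	.	DP=18;AO=18
ctg1	1000	.	C	A	29	.	DP=9;AO=3
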