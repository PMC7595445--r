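##fileformat=VCFv4.2
##contig=<ID=2L>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
2L	100	.	A	C	.	PASS	.	GT	0/0	0/1	1/1
2L	250	.	G	GTT	.	PASS	.	GT	0/0	0/0	0/1
2L	300	.	T	A,G	.	PASS	.	GT	1/2	0/1	0/0
2L	450	.	C	T	.	PASS	.	GT	0/1	./.	1|0
2L	600	.	G	A	.	PASS	.	GT	1/1	1/1	0/0
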