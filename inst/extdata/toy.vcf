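##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	100	m1	A	G	.	PASS	.	GT	0/0	0/1	1/1
1	200	m2	C	T	.	PASS	.	GT	./.	1/1	0/1
1	300	m3	G	A,T	.	PASS	.	GT	0/1	0/2	1/2
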