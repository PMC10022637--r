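##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10
1	100	m01	A	G	.	PASS	.	GT	./.	0/1	0/1	1/1	0/0	0/0	0/1	0/0	0/0	0/1
1	200	m02	C	T	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	300	m03	G	A	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	400	m04	T	C	.	PASS	.	GT	./.	./.	0/1	1/1	0/0	0/1	0/0	1/1	0/1	0/0
1	500	m05	A	C	.	PASS	.	GT	0/0	0/1	1/1	0/1	0/0	1/1	0/1	0/0	0/1	1/1
1	600	m06	A	T	.	PASS	.	GT	1/1	0/0	0/1	0/0	1/1	0/1	0/0	0/1	1/1	0/0
1	700	m07	C	G	.	PASS	.	GT	0/1	1/1	0/0	0/1	0/1	0/0	1/1	0/0	0/1	0/1
1	800	m08	G	T	.	PASS	.	GT	0/0	0/0	0/1	0/1	1/1	0/0	0/1	1/1	0/0	0/1
1	900	m09	T	A	.	PASS	.	GT	0/1	0/1	0/0	1/1	0/0	0/1	0/0	0/1	1/1	0/0
1	1000	m10	A	G	.	PASS	.	GT	1/1	0/1	0/1	0/0	0/1	0/0	0/1	0/0	0/1	1/1
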