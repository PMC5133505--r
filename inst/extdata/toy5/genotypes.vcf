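##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5	s6	s7	s8
1	4999	v2	A	C	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	5000	v1	A	C	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/1
1	25000	v3	G	T	.	PASS	.	GT	0/0	0/1	1/1	0/0	0/0	0/1	0/0	0/0
1	25001	v4	G	T	.	PASS	.	GT	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0
1	55000	v5	A	G	.	PASS	.	GT	0/0	0/0	0/1	0/1	0/0	0/0	1/1	0/0
1	57000	v6	C	T	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	95000	v7	A	C	.	PASS	.	GT	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0
1	124999	v8	T	A	.	PASS	.	GT	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0
1	175000	v9	C	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
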