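##fileformat=VCFv4.2
##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2
chr1	100	.	A	G	99	PASS	MQ=60	GT:DP	0/1:30	1/1:30
chr1	200	.	C	T	99	PASS	MQ=60	GT:DP	./.:30	0/1:30
chr1	300	.	G	A,T	99	PASS	MQ=60	GT:DP	0/1:30	0/2:30
chr1	400	.	T	C	10	PASS	MQ=60	GT:DP	0/1:30	0/0:30
chr1	500	.	A	C	99	PASS	MQ=10	GT:DP	0/1:30	0/0:30
chr1	600	.	G	T	99	PASS	MQ=60	GT:DP	0/1:1	0/1:30
chr1	700	.	C	G	99	PASS	MQ=60	GT:DP	0/1:300	0/1:300
chr1	800	.	T	A	99	PASS	MQ=60	GT:DP	1/1:30	0/1:30
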