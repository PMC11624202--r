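##fileformat=VCFv4.2
##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5	s6	s7	s8	s9	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20	s21	s22	s23	s24
chr1	100	.	A	G	99	PASS	MQ=60	GT:DP	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30
chr1	200	.	C	T	99	PASS	MQ=60	GT:DP	0/0:30	0/0:30	0/0:30	0/0:30	0/0:30	0/0:30	0/0:30	0/0:30	0/0:30	0/0:30	0/0:30	0/0:30	1/1:30	1/1:30	1/1:30	1/1:30	1/1:30	1/1:30	1/1:30	1/1:30	1/1:30	1/1:30	1/1:30	1/1:30
chr1	300	.	G	A	99	PASS	MQ=60	GT:DP	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30	0/0:30	0/1:30
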