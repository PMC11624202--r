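# chrom	pos	ancestral
chr1	100	A
chr1	800	A
chr1	900	N
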