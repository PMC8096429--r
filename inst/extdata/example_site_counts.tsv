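sample	chrom	pos	ref	alt	gene	coverage	alt_count
s1	2	25457242	C	T	DNMT3A	90	45
s1	2	25457243	G	A	DNMT3A	85	14
s2	17	7577120	C	T	TP53	110	3
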