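snp	effect_allele	beta
rs0281692	T	-0.2352
rs0625595	G	0.2189
rs0364929	T	-0.2083
rs0450431	T	-0.2095
rs0994691	T	-0.0829
rs0650722	A	0.0616
rs0357588	G	-0.0069
rs0591630	T	-0.1606
rs0657085	C	0.0249
rs0648580	T	0.0559
rs0556392	T	-0.0036
rs0752216	G	0.122
rs0968831	T	-0.0425
rs0156069	A	-0.433
rs0603717	G	0.0761
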