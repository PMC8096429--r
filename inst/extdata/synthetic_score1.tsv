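snp	effect_allele	beta
rs0695277	G	-0.1894
rs0573166	A	-0.2581
rs0425441	G	0.1963
rs0399404	A	0.0179
rs0334900	A	0.253
rs0162500	C	0.033
rs0738710	C	0.0225
rs0736622	T	0.1323
rs0399653	T	-0.0399
rs0670702	A	0.0252
rs0412263	A	0.0409
rs0122835	A	-0.0396
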