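snp	effect_allele	beta
rs0035197	T	0.1631
rs0319559	A	-0.1609
rs0481320	A	-0.1782
rs0635736	G	-0.2091
rs0971862	A	0.0525
rs0703872	G	0.0059
rs0171589	C	-0.2485
rs0129347	C	0.0626
rs0944295	T	-0.0559
rs0390338	G	-0.0497
rs0310765	T	0.167
rs0683884	C	0.056
rs0207825	T	0.1743
rs0640235	G	0.1707
rs0958962	G	0.3174
rs0108291	T	0.2046
rs0243676	A	-0.0405
rs0513304	T	0.0956
rs0223406	C	-0.0852
rs0671655	A	-0.0539
rs0868628	G	-0.0231
rs0333572	C	0.0051
rs0208317	T	-0.0198
rs0287274	G	-0.0923
rs0658092	T	-0.1706
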