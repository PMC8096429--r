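snp	effect_allele	beta
rs0216336	C	-0.1297
rs0530316	C	0.1344
rs0097593	T	-0.0457
rs0547015	G	-0.0167
rs0703908	C	-0.0861
rs0861389	A	-0.0184
rs0950035	G	0.015
rs0247306	C	0.2086
rs0090769	G	0.0734
rs0649814	T	-0.2344
rs0859709	T	0.2046
rs0212334	T	0.043
rs0737073	G	-0.2059
rs0158775	A	-0.097
rs0462129	T	-0.0576
rs0966637	G	0.0251
rs0029882	A	-0.1078
rs0028530	C	-0.0407
rs0493764	C	0.2024
rs0604216	C	0.1342
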