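snp	effect_allele	beta
rs0331119	C	-0.0597
rs0070352	G	0.0224
rs0060282	G	-0.2354
rs0125507	T	0.1256
rs0760538	T	0.2453
rs0271759	G	-0.1289
rs0432399	A	0.2171
rs0251696	G	0.1509
rs0989903	T	-0.0427
rs0517670	C	0.0834
rs0454086	A	-0.2317
rs0178292	A	0.0516
rs0085625	A	0.0648
rs0734653	G	0.101
rs0170538	C	-0.0282
rs0109881	T	0.0505
rs0552608	G	0.1644
rs0174841	A	-0.2482
rs0987828	A	0.2919
rs0566094	G	-0.1278
rs0720916	A	-0.0157
rs0349720	T	0.1951
rs0234098	T	-0.0962
rs0784133	C	-0.0102
rs0604422	C	-0.1017
rs0348361	A	-0.2074
rs0831300	A	0.0496
rs0353551	T	0.1072
rs0178799	G	0.0098
rs0678498	A	0.0662
rs0534292	A	-0.0802
rs0243962	C	-0.0856
rs0165328	G	-0.0811
rs0970819	A	0.027
rs0360365	T	-0.1474
rs0761949	G	0.1782
rs0661028	A	0.2648
rs0751372	T	-0.183
rs0673203	G	-0.2222
rs0111673	A	-0.3404
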