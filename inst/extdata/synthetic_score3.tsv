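snp	effect_allele	beta
rs0994958	T	-0.097
rs0140251	G	0.2011
rs0171161	C	0.1357
rs0049927	C	-0.0057
rs0255035	G	0.1032
rs0101342	G	0.2845
rs0216938	A	-0.0545
rs0897216	A	-0.1019
rs0758510	C	0.1665
rs0270636	A	0.1662
rs0668877	T	0.2095
rs0387709	C	0.0052
rs0165348	T	0.1943
rs0155199	G	-0.2616
rs0122115	A	-0.0486
rs0057886	T	0.1614
rs0381544	A	0.0266
rs0856886	C	-0.092
rs0465114	T	0.0529
rs0800870	C	-7e-04
rs0603894	A	-0.007
rs0423496	C	-0.2602
rs0374011	C	0.129
rs0807265	G	-0.275
rs0144249	A	-0.1756
rs0845690	G	-0.434
rs0085977	A	0.1112
rs0826894	A	-0.0859
rs0745489	A	0.0341
rs0833734	T	0.1773
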