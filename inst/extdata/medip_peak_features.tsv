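# Published number of MACS peaks overlapping each genome feature, per
# line (percentages in the source are counts over the line's total
# peaks).
feature	P1	P2	H1	H2	H3	L1	L2
Promoter	2841	2487	3031	2998	2905	2514	2427
5UTR	588	375	659	732	590	755	347
CDS	2392	1999	2561	2899	2318	2524	1845
Intron	1768	1441	1840	1941	1650	1661	1383
3UTR	339	276	345	327	330	320	284
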