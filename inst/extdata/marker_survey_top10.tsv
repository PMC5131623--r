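rank_printed	marker	mclass	bases_mean	bases_min	bases_max	aligned_bp	variable_n	variable_pct	pis_n	pis_pct	k80_mean	rf_to_reference	bootstrap_mean
1	trnS-trnG spacer	spacer	780	628	884	1125	438	38.9	128	11.4	0.104	4	82
2	ndhF-rpl32 spacer	spacer	898	849	965	1266	507	40.0	171	13.5	0.114	6	71
3	trnG intron	intron	762	743	790	846	236	27.9	76	9.0	0.059	4	75
4	ndhC-trnV spacer	spacer	734	504	821	991	330	33.3	98	9.9	0.081	4	63
5	ndhA intron	intron	1016	939	1045	1127	250	22.2	74	6.6	0.046	4	64
6	trnG-atpA spacer	spacer	641	550	750	895	353	39.4	136	15.2	0.114	6	65
7	atpH-atpI spacer	spacer	898	638	980	1178	323	27.4	92	7.8	0.062	8	76
8	psbE-petL spacer	spacer	1058	570	1165	1396	381	27.3	132	9.5	0.068	8	70
9	petA-psbJ spacer	spacer	736	420	944	1062	285	26.8	90	8.5	0.076	8	76
10	trnE-trnT spacer	spacer	842	478	1029	1345	406	30.2	121	9.0	0.089	8	63
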