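species	accession	coverage	lsc_bp	lsc_gc	ssc_bp	ssc_gc	ir_bp	ir_gc	full_bp	full_gc
Allomaieta villosa	KX826819	278	85915	0.347	16975	0.306	26781	0.425	156452	0.369
Bertolonia acuminata	KX826820	189	85571	0.347	17008	0.308	26733	0.425	156045	0.370
Blakea schlimii	KX826821	170	85370	0.349	16998	0.308	26747	0.425	155862	0.370
Eriocnema fulva	KX826822	42	85431	0.348	16953	0.308	26805	0.425	155994	0.370
Graffenrieda moritziana	KX826823	683	85341	0.347	16924	0.309	26734	0.425	155733	0.370
Henriettea barkeri	KX826824	130	85991	0.347	17036	0.306	26750	0.425	156527	0.369
Merianthera pulchra	KX826825	56	85621	0.348	17001	0.307	26773	0.424	156168	0.370
Miconia dodecandra	KX826826	318	86609	0.348	16999	0.310	26804	0.425	157216	0.370
Nepsera aquatica	KX826827	705	84644	0.348	17066	0.310	26700	0.426	155110	0.371
Opisthocentra clidemioides	KX826828	100	85866	0.348	16942	0.309	26772	0.425	156352	0.370
Pterogastra divaricata	KX826829	184	84718	0.351	17156	0.312	26537	0.425	154948	0.372
Rhexia virginica	KX826830	683	84459	0.351	16924	0.311	26626	0.425	154635	0.372
Rhynchanthera bracteata	KX826831	304	85093	0.347	16729	0.307	26643	0.426	155108	0.370
Salpinga maranoniensis	KX826832	537	85128	0.353	16653	0.317	25765	0.428	153311	0.374
Tibouchina longifolia	KX826833	195	86297	0.349	17124	0.311	26684	0.425	156789	0.371
Triolena amazonica	KX826834	48	86200	0.347	16970	0.307	26741	0.425	156652	0.369
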