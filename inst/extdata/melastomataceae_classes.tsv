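species	coding_bp	coding_gc	trna_bp	trna_gc	rrna_bp	rrna_gc	intron_bp	intron_gc	intergenic_bp	intergenic_gc
Allomaieta villosa	80826	0.374	3348	0.497	9050	0.425	20553	0.347	42675	0.316
Bertolonia acuminata	80670	0.375	3356	0.497	9050	0.425	20437	0.347	42532	0.316
Blakea schlimii	80742	0.375	3348	0.498	9050	0.425	20541	0.347	42181	0.319
Eriocnema fulva	80628	0.375	3354	0.497	9050	0.425	20540	0.347	42422	0.318
Graffenrieda moritziana	80286	0.375	3349	0.497	9050	0.425	19691	0.347	43357	0.317
Henriettea barkeri	80781	0.374	3363	0.495	9050	0.425	20571	0.347	42762	0.315
Merianthera pulchra	80751	0.375	3364	0.498	9050	0.425	20478	0.347	42525	0.318
Miconia dodecandra	80586	0.376	3354	0.498	9050	0.425	20548	0.347	43678	0.317
Nepsera aquatica	80646	0.375	3370	0.496	9050	0.425	20619	0.347	41425	0.318
Opisthocentra clidemioides	80643	0.376	3360	0.496	9050	0.425	20641	0.347	42658	0.317
Pterogastra divaricata	80427	0.377	3339	0.498	9050	0.425	19911	0.347	42221	0.318
Rhexia virginica	80466	0.377	3353	0.496	9050	0.425	20260	0.347	41506	0.319
Rhynchanthera bracteata	80415	0.375	3241	0.502	9048	0.425	20538	0.347	41866	0.317
Salpinga maranoniensis	79326	0.376	3349	0.500	9050	0.425	18991	0.347	42595	0.326
Tibouchina longifolia	80682	0.377	3348	0.497	9050	0.425	20666	0.347	43043	0.317
Triolena amazonica	80619	0.375	3337	0.496	9050	0.425	20476	0.347	43170	0.316
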