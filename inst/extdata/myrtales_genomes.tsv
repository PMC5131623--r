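family	species	accession	n_coding	n_trna	n_rrna	lsc_bp	ssc_bp	ir_bp	full_bp
Melastomataceae	Miconia dodecandra	KX826826	84	37	8	86609	16999	26804	157216
Myrtaceae	Allosyncarpia ternata	NC022413	84	37	8	88218	18571	26402	159563
Myrtaceae	Angophora costata	NC022412	84	37	8	88769	18773	26392	160326
Myrtaceae	Corymbia gummifera	NC022407	84	37	8	88310	17197	27603	160713
Myrtaceae	Eucalyptus polybractea	NC022393	84	37	8	88944	18530	26397	160268
Myrtaceae	Eugenia uniflora	NC027744	84	37	8	87459	18318	26334	158445
Lythraceae	Lagerstroemia fauriei	NC029808	84	37	8	83923	16933	25792	152440
Onagraceae	Oenothera grandiflora	NC029211	84	38	8	89862	19035	28824	166545
Myrtaceae	Stockwellia quadrifida	NC022414	84	37	8	88247	18544	26385	159561
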