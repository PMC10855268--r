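tissue	family	max_group_mean	log2_fold_change	fold_change	p_value	fdr_p_value
eye	Xanthobacteraceae	810	6.26	77	0.0000	0.0005
eye	Comamonadaceae	1200	6.05	66	0.0001	0.0013
eye	Oxalobacteraceae	100	5.19	37	0.0017	0.0092
eye	Corynebacteriaceae	530	9.20	590	0.0041	0.0147
eye	Propionibacteriaceae	440	3.96	16	0.0042	0.0147
eye	Rhizobiaceae	140	10.43	1400	0.0089	0.0234
skin	Flavobacteriaceae	350	6.53	92	0.0040	0.0228
skin	Pseudoalteromonadaceae	420	3.22	9.3	0.0042	0.0228
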