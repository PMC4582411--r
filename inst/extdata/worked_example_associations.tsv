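study_id	exposure	outcome	beta	se	n	scale	covariates
worked_example	score_synthesis	ln25ohd	2.830000000000000071	0.1785747099236289770	51122	percent_per_allele	published
worked_example	score_synthesis	sbp	-0.100000000000000006	0.0535469023042424441	146581	per_allele	published
worked_example	score_synthesis	dbp	-0.080000000000000002	0.0331638747001025136	146581	per_allele	published
worked_example	score_synthesis	hypertension	-0.020202707317519466	0.0078500571718349531	142255	log_odds_per_allele	published
worked_example	ln25ohd	sbp	-0.119999999999999996	0.0408170765539723271	49363	per_10pct	published
worked_example	ln25ohd	dbp	-0.020000000000000000	0.0280617401308559736	49363	per_10pct	published
worked_example	ln25ohd	hypertension	-0.020202707317519466	0.0052064404734448446	49363	log_odds_per_10pct	published
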