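gene_id	description	rpkm_cured	rpkm_infected	printed_fold	printed_consistent
cas7	CRISPR-associated protein Cas7	205.31	53.85	3.81	TRUE
cas5	CRISPR-associated protein Cas5	146.69	25.36	5.79	FALSE
cas4	CRISPR-associated protein Cas4	95.30	20.38	4.68	TRUE
cas2	CRISPR-associated protein Cas2	126.33	7.35	17.19	TRUE
cbass1_cyclase	CBASS_1 cyclase	45.85	5.53	8.29	TRUE
cbass1_effector	CBASS_1 effector	66.68	23.89	2.79	TRUE
cbass2_cyclase	CBASS_2 cyclase	343.63	23.56	14.58	FALSE
hachiman_a	DUF1837 domain-containing protein / Hachiman A	347.90	13.25	26.25	FALSE
hachiman_b	DEAD/DEAH box helicase / Hachiman B	222.52	30.53	7.29	TRUE
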