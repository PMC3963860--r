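cell_type	gene_symbol	ct	ct_sd	delta_ct	delta_ct_sd	fold	fold_sd
TG1	LPHN2	24	0.3	2.88	0.58	7.36	1.49
TG1	GPR56	24.2	0.04	3.08	0.32	8.46	1.25
OB1	F2R	24.3	0.01	3.18	0.28	9.06	1.22
OB1	GPR56	24.4	0.01	3.28	0.29	9.71	1.22
OB1	FZD7	24.5	0.03	3.38	0.31	10.41	1.24
OB1	LPHN2	24.6	0.04	3.48	0.32	11.16	1.25
f-NSC	GPR56	22.6	0.08	1.48	0.36	2.79	1.28
f-NSC	FZD3	24.7	0.18	3.58	0.46	12.38	1.38
f-NSC	GPRC5B	24.8	0.15	3.68	0.43	13.09	1.35
HA	FZD1	25	0.08	3.88	0.36	14.72	1.28
HA	FZD7	25	0.1	3.88	0.38	14.72	1.3
U87	BDKRB2	24.5	0.3	3.38	0.58	10.41	1.49
U87	GPR56	24.9	0.13	3.78	0.41	13.74	1.33
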