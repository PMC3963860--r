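gene_symbol	accession	mw_kda	expected_peptides	cell_type	units	peptides	spectra
GPR56	Q9Y653	78	14	OB1	42820	4	8
GPR56	Q9Y653	78	14	TG1	52347	4	10
GPR56	Q9Y653	78	14	f-NSC	155121	8	37
GPR56	Q9Y653	78	14	HA	625		
GPR56	Q9Y653	78	14	U87	32369	3	6
LPHN2	O95490	163	50	OB1	37915	9	15
LPHN2	O95490	163	50	TG1	62684	12	24
LPHN2	O95490	163	50	f-NSC	2338		
LPHN2	O95490	163	50	HA	5921		
LPHN2	O95490	163	50	U87	3495		
F2R	P25116	44	5	OB1	48045	2	6
F2R	P25116	44	5	TG1	26751		
F2R	P25116	44	5	f-NSC	18912		
F2R	P25116	44	5	HA	7701		
F2R	P25116	44	5	U87	1259		
BDKRB2	P30411	44	0	OB1	78		
BDKRB2	P30411	44	0	TG1	0		
BDKRB2	P30411	44	0	f-NSC	1		
BDKRB2	P30411	44	0	HA	1655		
BDKRB2	P30411	44	0	U87	42664		
FZD7	O75084	61	3	OB1	39613		
FZD7	O75084	61	3	TG1	10182		
FZD7	O75084	61	3	f-NSC	14788		
FZD7	O75084	61	3	HA	30943		
FZD7	O75084	61	3	U87	4011		
GPRC5B	Q9NZH0	41	3	OB1	24853	1	3
GPRC5B	Q9NZH0	41	3	TG1	24463	1	4
GPRC5B	Q9NZH0	41	3	f-NSC	33650	3	7
GPRC5B	Q9NZH0	41	3	HA	2888		
GPRC5B	Q9NZH0	41	3	U87	248		
TM7SF1	O60478	45	3	OB1	15303		
TM7SF1	O60478	45	3	TG1	3322		
TM7SF1	O60478	45	3	f-NSC	29968		
TM7SF1	O60478	45	3	HA	2855		
TM7SF1	O60478	45	3	U87	1743		
CXCR4	P61073	40	2	OB1	29644		
CXCR4	P61073	40	2	TG1	14193		
CXCR4	P61073	40	2	f-NSC	11354		
CXCR4	P61073	40	2	HA	120		
CXCR4	P61073	40	2	U87	19		
BAI2	O60241	173	40	OB1	19770		
BAI2	O60241	173	40	TG1	15863		
BAI2	O60241	173	40	f-NSC	29243	1	1
BAI2	O60241	173	40	HA	5050		
BAI2	O60241	173	40	U87	5478		
BDKRB1	P46663	40	2	OB1	5		
BDKRB1	P46663	40	2	TG1	0		
BDKRB1	P46663	40	2	f-NSC	9		
BDKRB1	P46663	40	2	HA	65		
BDKRB1	P46663	40	2	U87	27717		
GPR153	Q6NV75	65	1	OB1	8111		
GPR153	Q6NV75	65	1	TG1	26080		
GPR153	Q6NV75	65	1	f-NSC	7762		
GPR153	Q6NV75	65	1	HA	2438		
GPR153	Q6NV75	65	1	U87	342		
CD97	P48960	90	19	OB1	14593	10	40
CD97	P48960	90	19	TG1	24958	9	31
CD97	P48960	90	19	f-NSC	405		
CD97	P48960	90	19	HA	1079		
CD97	P48960	90	19	U87	5233	6	21
LGR4	Q8N537	104	8	OB1	22726		
LGR4	Q8N537	104	8	TG1	4135		
LGR4	Q8N537	104	8	f-NSC	19526		
LGR4	Q8N537	104	8	HA	1804		
LGR4	Q8N537	104	8	U87	51		
CNR1	P21554	53	3	OB1	20381		
CNR1	P21554	53	3	TG1	3161		
CNR1	P21554	53	3	f-NSC	14232		
CNR1	P21554	53	3	HA	190		
CNR1	P21554	53	3	U87	1		
CELSR2	Q9HCU4	317	79	OB1	7543	2	2
CELSR2	Q9HCU4	317	79	TG1	1769	2	2
CELSR2	Q9HCU4	317	79	f-NSC	3501	8	12
CELSR2	Q9HCU4	317	79	HA	601		
CELSR2	Q9HCU4	317	79	U87	118		
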