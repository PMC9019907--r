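cohort	n_cohort	characteristic	category	count	percent
TCGA	566	age	>=60	316	55.83
TCGA	566	age	<60	249	43.99
TCGA	566	age	unknown	1	0.18
TCGA	566	sex	male	415	73.32
TCGA	566	sex	female	151	26.68
TCGA	566	stage	I-II	135	23.85
TCGA	566	stage	III-IV	417	73.67
TCGA	566	stage	unknown	14	2.47
TCGA	566	signature	LR	195	34.45
TCGA	566	signature	HR	371	65.55
Leipzig	270	age	>=60	117	43.33
Leipzig	270	age	<60	153	56.67
Leipzig	270	sex	male	223	82.59
Leipzig	270	sex	female	47	17.41
Leipzig	270	stage	I-II	55	20.37
Leipzig	270	stage	III-IV	215	79.63
Leipzig	270	signature	LR	101	37.41
Leipzig	270	signature	HR	169	62.59
FHCRC	97	age	>=60	47	48.45
FHCRC	97	age	<60	50	51.55
FHCRC	97	sex	male	66	68.04
FHCRC	97	sex	female	31	31.96
FHCRC	97	stage	I-II	41	42.27
FHCRC	97	stage	III-IV	56	57.73
FHCRC	97	signature	LR	31	31.96
FHCRC	97	signature	HR	66	68.04
MDACC	74	age	>=60	37	50.00
MDACC	74	age	<60	37	50.00
MDACC	74	sex	male	58	78.38
MDACC	74	sex	female	16	21.62
MDACC	74	stage	I-II	19	25.68
MDACC	74	stage	III-IV	55	74.32
MDACC	74	signature	LR	19	25.68
MDACC	74	signature	HR	55	74.32
KHUMC	72	age	>=60	44	61.11
KHUMC	72	age	<60	27	37.50
KHUMC	72	age	unknown	1	1.39
KHUMC	72	sex	male	54	75.00
KHUMC	72	sex	female	18	25.00
KHUMC	72	stage	I-II	24	33.33
KHUMC	72	stage	III-IV	30	41.67
KHUMC	72	stage	unknown	18	25.00
KHUMC	72	signature	LR	27	37.5
KHUMC	72	signature	HR	45	62.5
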