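name	network	x	y	z	radius	is_seed
SMA	SMN	0	-21	48	5	FALSE
L_motor	SMN	-39	-26	51	5	FALSE
R_motor	SMN	38	-26	48	5	FALSE
MPFC	DMN	-1	54	27	5	TRUE
PCC	DMN	0	-52	27	5	TRUE
L_parietal	DMN	-46	-66	30	5	FALSE
R_parietal	DMN	49	-63	33	5	FALSE
dmPFC	FPN	0	24	46	5	FALSE
FPN_L_aPFC	FPN	-44	45	0	5	FALSE
FPN_R_aPFC	FPN	44	45	0	5	FALSE
L_sup_parietal	FPN	-50	-51	45	5	FALSE
R_sup_parietal	FPN	50	-51	45	5	FALSE
dACC	SN	0	21	36	5	FALSE
SN_L_aPFC	SN	-35	45	30	5	FALSE
SN_R_aPFC	SN	32	45	30	5	FALSE
L_insula	SN	-41	3	6	5	FALSE
R_insula	SN	41	3	6	5	FALSE
L_visual	VIS	-7	83	2	5	FALSE
R_visual	VIS	7	83	2	5	FALSE
L_auditory	AUD	-62	-30	12	5	FALSE
R_auditory	AUD	59	-27	15	5	FALSE
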