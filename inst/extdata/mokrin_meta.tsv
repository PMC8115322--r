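individual	burial	group	sex	age_class	status	mt_haplotype	y_haplotype	depth
122E	122E	SW	XY	infans	prestigious	U5a2b1a	I2a1b	1.09
122S	122S	SW	XX	maturus	.	H32	.	0.78
161	161	SE	XX	infans	prestigious	H80	.	1.20
163	163	SE	XY	adultus	prestigious	U4a2	J2b	1.21
181	181	SE	XX	adultus	prestigious	U4a2	.	0.62
186	186	SW	XX	infans	.	H1aj	.	0.33
211	211	SW	XY	maturus	.	U5a2b1a	I2a1b	0.79
220	220	SW	XY	juvenis	simple	T2b11	R1b1a2a2c1	0.64
223	223	SW	XX	infans	.	U3a1	.	0.39
224	224	SW	XX	adultus	simple	T2b	.	0.77
225	225	SW	XY	adultus	simple	J1b1a1	R1b1a2a2c1	0.82
228	228	SW	XX	maturus	prestigious	J1c	.	0.95
237	237	SW	XX	juvenis	.	T2b	.	0.89
243	243	NW	XY	adultus	prestigious	H	BT	1.12
246	246	SW	XX	maturus	.	H80	.	0.98
247	247	SW	XX	infans	.	H1	.	0.90
257A	257A	NW	XX	adultus	simple	H	.	0.60
257B	257B	NW	XY	infans	.	K1a4	R1b1a2a2c1a1	0.61
260	260	NW	XY	juvenis	simple	J1c	I2a2a1a2a2	0.92
282	282	NE	XY	juvenis	simple	H2b	BT	1.41
287	287	NE	XX	adultus	.	U5b2a2c	.	0.81
288	288	NE	XX	senior	prestigious	HV0e	.	0.81
295	295	SE	XY	juvenis	simple	H80	I2a1a	0.82
302	302	SE	XX	adultus	prestigious	J1c	.	0.89
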