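population	african_pct	european_pct	native_american_pct	east_asian_pct
Afro-Ecuadorian	49.53	13.85	35.86	0.76
Mestizo	2.39	29.97	66.11	1.52
Montubio	9.89	38.08	51.36	0.67
Tsachila	1.88	10.66	87.12	0.35
African American (ASW)	76.25	19.52	3.17	1.06
African Caribbean (ACB)	88.62	10.92	0.07	0.39
Colombia (CLM)	9.01	64.75	25.22	1.03
Mexico (MXL)	4.8	46.23	44.52	4.45
Peru (PEL)	3.01	20.36	73.76	2.87
Puerto Rico (PUR)	15.01	71.5	12.82	0.67
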