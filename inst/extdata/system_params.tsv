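tissue	V_total	f_vasc	f_EW	pct_CO	pct_lymph	r_small	r_large	n_small_per_large	well_stirred
adipose	22.7	0.031	0.141	5.00	12.8	7.0	20	500	FALSE
bone	3.95	0.05	0.098	5.00	0.00	9.0	33	46	TRUE
brain	1.34	0.05	0.092	12.0	1.05	0.6	18	20000000	FALSE
gut	1.22	0.05	0.267	15.0	12.0	4.8	25	500	FALSE
heart	0.359	0.042	0.313	4.00	1.00	4.8	25	400	FALSE
kidney	0.325	0.07	0.283	19.0	8.50	7.4	20	200	FALSE
liver	1.61	0.05	0.165	25.5	33.0	9.0	33	46	FALSE
lung	0.547	0.185	0.348	100	3.00	9.0	25	45	FALSE
muscle	31.3	0.027	0.091	17.0	16.0	4.5	22	2000	FALSE
pancreas	0.123	0.05	0.12	1.00	0.30	6.0	20	3610	FALSE
skin	3.15	0.05	0.623	5.00	7.30	6.0	20	500	FALSE
spleen	0.150	0.05	0.208	2.00	0.00	9.0	33	46	TRUE
sc_site	0.005	0.05	0.623	0.016	0.0392	5.0	20	500	FALSE
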