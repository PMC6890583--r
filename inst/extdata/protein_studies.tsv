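protein	mw_kda	rs_nm	pI	dose	dose_unit	reference	pred_cmax	cmax_unit	pred_tmax_h	fe_cmax	fe_tmax
IGF-1	7.6	1.56	8.2	0.040	mg_per_kg	ref37	0.188	mg_per_L	4.59	1.11	0.62
IGF-1	7.6	1.56	8.2	0.080	mg_per_kg	ref37	0.377	mg_per_L	4.58	1.24	0.69
IGF-1	7.6	1.56	8.2	0.050	mg_per_kg	ref38	0.235	mg_per_L	4.59	0.82	1.38
IGF-1	7.6	1.56	8.2	0.100	mg_per_kg	ref38	0.471	mg_per_L	4.58	1.13	1.02
IGF-1	7.6	1.56	8.2	0.040	mg_per_kg	ref39	0.188	mg_per_L	4.59	1.26	0.67
IGF-1	7.6	1.56	8.2	0.080	mg_per_kg	ref39	0.377	mg_per_L	4.58	1.54	0.65
IL-2	15.5	2.07	7.7	0.0292	mg_per_m2	ref40	0.000316	mg_per_L	2.70	1.21	0.68
IL-2	15.5	2.07	7.7	0.0583	mg_per_m2	ref40	0.000632	mg_per_L	2.70	3.08	0.67
IL-2	15.5	2.07	7.7	3.00	mg	ref41	0.0188	mg_per_L	2.70	1.53	0.68
IL-2	15.5	2.07	7.7	3.75	mg	ref41	0.0235	mg_per_L	2.70	1.33	0.67
IL-2	15.5	2.07	7.7	4.50	mg	ref41	0.0282	mg_per_L	2.70	1.97	0.45
Anakinra	17.3	2.16	5.5	100	mg	ref42	0.782	mg_per_L	2.93	1.01	0.73
IL-10	18.7	2.23	7.4	0.008	mg_per_kg	ref43	0.00397	mg_per_L	4.18	1.46	0.52
IL-10	18.7	2.23	7.4	1.75	mg	ref44	0.0108	mg_per_L	4.19	0.58	0.84
IL-10	18.7	2.23	7.4	0.001	mg_per_kg	ref45	0.000496	mg_per_L	4.17	2.43	0.52
IL-10	18.7	2.23	7.4	0.0025	mg_per_kg	ref45	0.00124	mg_per_L	4.18	1.43	0.84
IL-10	18.7	2.23	7.4	0.005	mg_per_kg	ref45	0.00248	mg_per_L	4.19	1.23	0.84
IL-10	18.7	2.23	7.4	0.010	mg_per_kg	ref45	0.00496	mg_per_L	4.18	1.19	0.84
IL-10	18.7	2.23	7.4	0.025	mg_per_kg	ref45	0.0124	mg_per_L	4.18	0.74	1.04
IL-10	18.7	2.23	7.4	0.050	mg_per_kg	ref45	0.0248	mg_per_L	4.19	0.92	0.84
IL-11	19	2.25	11.2	0.003	mg_per_kg	ref46	0.00108	mg_per_L	2.89	0.94	2.89
IL-11	19	2.25	11.2	0.010	mg_per_kg	ref46	0.00361	mg_per_L	2.89	0.94	1.44
IL-11	19	2.25	11.2	0.025	mg_per_kg	ref46	0.00902	mg_per_L	2.89	1.17	1.44
IL-11	19	2.25	11.2	0.050	mg_per_kg	ref46	0.0180	mg_per_L	2.88	1.01	1.44
hGH	22	2.38	5.27	600	mIU	ref47	1.69	mIU_per_L	2.77	0.64	0.65
hGH	22	2.38	5.27	1200	mIU	ref47	2.87	mIU_per_L	2.77	0.52	0.58
hGH	22	2.38	5.27	1800	mIU	ref47	5.67	mIU_per_L	2.77	0.68	0.48
hGH	22	2.38	5.27	0.033	mg_per_kg	ref48	0.00838	mg_per_L	2.77	0.71	0.52
hGH	22	2.38	5.27	200	mIU_per_kg	ref60	50.8	mIU_per_L	2.77	0.48	0.69
hGH	22	2.38	5.27	1.30	mg_per_m2	ref49	0.00708	mg_per_L	2.77	0.40	0.56
EPO	30.4	2.70	8.75	0.000313	mg_per_kg	ref51	0.000280	mg_per_L	10.98	1.24	0.84
EPO	30.4	2.70	8.75	0.000938	mg_per_kg	ref52	0.000839	mg_per_L	10.97	1.08	0.61
EPO	30.4	2.70	8.75	0.00188	mg_per_kg	ref52	0.00201	mg_per_L	10.97	1.25	0.61
EPO	30.4	2.70	8.75	0.00188	mg_per_kg	ref50	0.00201	mg_per_L	10.97	0.91	0.84
EPO	30.4	2.70	8.75	0.00281	mg_per_kg	ref50	0.00391	mg_per_L	10.96	0.63	0.84
EPO	30.4	2.70	8.75	0.00375	mg_per_kg	ref50	0.00494	mg_per_L	10.97	0.70	0.33
EPO	30.4	2.70	8.75	0.00563	mg_per_kg	ref50	0.00867	mg_per_L	10.97	0.78	0.65
EPO	30.4	2.70	8.75	0.0075	mg_per_kg	ref50	0.0117	mg_per_L	10.96	0.84	0.37
EPO	30.4	2.70	8.75	0.00844	mg_per_kg	ref50	0.0153	mg_per_L	10.96	0.77	0.65
EPO	30.4	2.70	8.75	0.0113	mg_per_kg	ref50	0.0233	mg_per_L	10.96	0.75	0.30
EPO	30.4	2.70	8.75	0.015	mg_per_kg	ref50	0.0373	mg_per_L	10.98	0.95	0.65
EPO	30.4	2.70	8.75	0.000188	mg_per_kg	ref53	0.000168	mg_per_L	10.98	1.28	0.92
EPO	30.4	2.70	8.75	0.000375	mg_per_kg	ref53	0.000335	mg_per_L	10.98	1.15	0.92
EPO	30.4	2.70	8.75	0.000625	mg_per_kg	ref53	0.00559	mg_per_L	10.96	1.24	0.91
Albumin	67	3.55	5.67	100	pct_dose	ref27	9.35	pct_dose	42.10	1.18	0.88
Tralokinumab	144	5.00	NA	150	mg	ref54	10.9	mg_per_L	62.53	0.64	0.52
Tralokinumab	144	5.00	NA	300	mg	ref54	21.7	mg_per_L	62.53	0.60	0.52
Etanercept	150	5.08	7.89	25	mg	ref55	1.45	mg_per_L	41.48	0.99	0.81
Etanercept	150	5.08	7.89	50	mg	ref56	2.90	mg_per_L	41.62	0.76	0.80
Etanercept	150	5.08	7.89	25	mg	ref57	1.45	mg_per_L	41.62	1.24	0.44
Etanercept	150	5.08	7.89	10	mg	ref58	0.580	mg_per_L	41.62	1.44	1.16
Adalimumab	144	5.00	8.25	40	mg	prescribing_info	3.12	mg_per_L	63.68	0.66	0.49
Omalizumab	145	5.01	7.03	150	mg	ref59	11.8	mg_per_L	70.78	0.78	0.59
Omalizumab	145	5.01	7.03	300	mg	ref59	23.5	mg_per_L	70.78	0.80	0.59
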