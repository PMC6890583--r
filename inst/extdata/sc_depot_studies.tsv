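protein	n_subjects	diameter_cm	K_pct_per_min	dosing_site	reference
Albumin	15	2.2	NA	Arm	ref27
IgG	8	1.41	0.157	Hand	ref28
IgG	14	1.70	0.093	Forearm	ref29
IgG	10	1.60	0.095	Hand	ref29
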