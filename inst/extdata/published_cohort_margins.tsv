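side_effect	k_male	k_female	p_sex_printed	age_endorsed_mean	age_endorsed_sd	age_not_mean	age_not_sd	p_age_printed
reduced_sex_drive	2251	6264	1.5e-08	41.0	13.98	44.4	16.01	1.1e-58
weight_gain	1402	5695	3.2e-29	41.9	13.89	43.6	15.96	1.1e-13
dry_mouth	1236	4544	3.2e-10	42.7	14.20	43.1	15.71	0.071
nausea	867	4352	1e-51	37.7	13.34	44.8	15.52	1.6e-187
headache	704	3282	3.1e-28	38.3	13.74	44.1	15.45	2e-106
dizziness	959	3930	5.2e-19	38.4	13.43	44.4	15.57	5.3e-130
shaking	571	2466	7.4e-15	38.8	14.22	43.7	15.37	3.8e-62
muscle_pain	234	837	0.045	42.0	14.98	43.1	15.33	0.029
sweating	997	3291	0.048	40.3	13.75	43.7	15.61	6.8e-38
vomiting	147	826	4.7e-12	35.7	12.65	43.4	15.34	6e-53
constipation	395	1489	2.70e-04	43.3	15.01	43.0	15.34	0.440
diarrhoea	368	1176	0.590	39.9	13.87	43.3	15.39	8.8e-17
drowsiness	1173	3709	0.480	39.7	14.30	44.0	15.46	6.8e-67
insomnia	1052	3672	1.00e-04	39.6	14.35	44.0	15.43	2.3e-70
anxiety	794	2973	1.5e-07	39.1	14.24	43.9	15.40	1.6e-68
agitation	786	2816	7.2e-05	39.6	14.12	43.7	15.45	1.3e-50
fatigue	912	3181	4.20e-04	39.4	14.49	43.9	15.38	8.4e-63
weight_loss	157	795	5.9e-09	36.1	13.42	43.3	15.32	5.1e-47
rash	97	257	0.190	45.5	14.96	43.0	15.31	0.002
runny_nose	82	344	0.012	44.9	15.64	43.0	15.30	0.010
blurred_vision	266	1012	0.002	42.6	14.60	43.0	15.35	0.280
suicidal_thoughts	699	2560	1.9e-05	38.2	14.24	43.9	15.33	4.7e-87
suicide_attempt	248	1090	2.4e-07	35.9	13.41	43.5	15.31	4.5e-69
other	632	1968	0.900	41.3	14.05	43.3	15.47	1.3e-09
none	334	1140	0.110	43.8	15.04	43.0	15.33	0.044
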