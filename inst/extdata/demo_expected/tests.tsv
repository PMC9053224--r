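side_effect	k_male	n_male	k_female	n_female	z_sex	p_sex	age_mean_endorsed	age_mean_not	p_age
reduced_sex_drive	197	339	602	1116	1.3511889	0.17663492	44.632541	43.571494	0.17850001
weight_gain	178	339	665	1116	-2.312779	0.020734795	44.205457	44.083497	0.87810079
dry_mouth	161	339	528	1116	0.058389083	0.95343871	44.454282	43.884204	0.46833744
nausea	145	339	614	1116	-3.9527454	7.7259619e-05	44.170092	44.136782	0.96618801
drowsiness	129	339	418	1116	0.19904697	0.84222601	45.054479	43.611784	0.074887914
insomnia	135	339	431	1116	0.39787558	0.6907219	45.175618	43.503825	0.037722001
dizziness	123	339	499	1116	-2.7477501	0.0060005728	44.602572	43.819328	0.32350539
fatigue	122	339	390	1116	0.3518239	0.72497033	45.983984	43.160657	0.00057779505
sweating	135	339	405	1116	1.1791284	0.23834707	44.398519	44.009945	0.63247642
headache	113	339	462	1116	-2.6599073	0.0078162163	44.362609	44.017955	0.66773079
suicidal_thoughts	100	339	310	1116	0.61678026	0.53737967	43.949268	44.234545	0.74370792
anxiety	97	339	354	1116	-1.0832535	0.27869591	43.909534	44.264044	0.6761778
agitation	103	339	334	1116	0.16010986	0.87279453	45.427002	43.60776	0.033490207
shaking	94	339	380	1116	-2.1750258	0.02962818	44.65	43.914577	0.37985989
constipation	64	339	186	1116	0.94571762	0.34429263	44.7836	44.023568	0.46511835
diarrhoea	52	339	146	1116	1.0613423	0.28853438	44.293434	44.13222	0.88801353
suicide_attempt	36	339	125	1116	-0.29877531	0.76511149	45.367702	44.003168	0.27540466
blurred_vision	54	339	155	1116	0.93805527	0.34821601	43.816746	44.210754	0.72480411
muscle_pain	36	339	113	1116	0.26275085	0.79274262	44.894631	44.069678	0.523994
vomiting	39	339	200	1116	-2.7926142	0.0052284009	44.312134	44.123109	0.85839412
weight_loss	42	339	164	1116	-1.066597	0.28615383	45.443689	43.941473	0.18202579
runny_nose	18	339	48	1116	0.78160049	0.4344494	44.015152	44.160763	0.93847085
rash	6	339	44	1116	-1.9233052	0.054441733	45.874	44.092954	0.4084569
other	80	339	255	1116	0.28702597	0.77409243	44.523582	44.043661	0.60674651
none	83	339	207	1116	2.3958005	0.016584115	44.351034	44.10515	0.80240486
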