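side_effect	reduced_model	loglik_full	loglik_reduced	aic_full	aic_reduced	delta_aic	lrt_stat	df	pvalue	converged_full	converged_reduced
sweating	ssri_only	-1947.0382	-1949.6247	3950.0765	3949.2494	-0.82707252	5.1729275	3	0.15956374	TRUE	TRUE
sweating	snri_only	-1947.0382	-1948.3471	3950.0765	3942.6942	-7.3823006	2.6176994	5	0.75867426	TRUE	TRUE
sweating	common_only	-1947.0382	-1950.9203	3950.0765	3941.8406	-8.2359133	7.7640867	8	0.45684769	TRUE	TRUE
nausea	ssri_only	-2352.2406	-2353.4452	4760.4811	4756.8904	-3.5907434	2.4092566	3	0.49191383	TRUE	TRUE
nausea	snri_only	-2352.2406	-2357.7889	4760.4811	4761.5779	1.0967554	11.096755	5	0.049495	TRUE	TRUE
nausea	common_only	-2352.2406	-2358.2189	4760.4811	4756.4377	-4.0434107	11.956589	8	0.1531513	TRUE	TRUE
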