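prs_trait	medication	side_effect	n	beta	se	odds_ratio	ci_low	ci_high	pvalue	r2_nagelkerke	ll_full	ll_null	converged	significant_nominal	significant_bonferroni	bonferroni_family
BMI	pooled	weight_gain	1455	0.039341512	0.084430172	1.0401256	0.88149268	1.2273061	0.6412405	0.00020240166	-972.28713	-972.3957	TRUE	FALSE	FALSE	per_drug_10
BMI	sertraline	weight_gain	829	-0.013619011	0.11412962	0.98647331	0.78874756	1.2337656	0.90501445	2.3696013e-05	-534.7728	-534.77992	TRUE	FALSE	FALSE	per_drug_10
BMI	escitalopram	weight_gain	647	-0.072568533	0.13104084	0.93000201	0.71935244	1.2023366	0.57972557	0.00065737335	-413.36186	-413.51532	TRUE	FALSE	FALSE	per_drug_10
BMI	venlafaxine	weight_gain	512	0.16437843	0.1522123	1.1786603	0.87463187	1.5883712	0.28017393	0.0031555347	-329.09497	-329.6806	TRUE	FALSE	FALSE	per_drug_10
BMI	fluoxetine	weight_gain	448	0.021163375	0.15406716	1.0213889	0.75517731	1.3814442	0.89074261	5.7929418e-05	-290.91829	-290.92773	TRUE	FALSE	FALSE	per_drug_10
BMI	citalopram	weight_gain	397	-0.1305263	0.1724636	0.87763341	0.62590996	1.230593	0.44914938	0.0019955816	-255.42347	-255.71057	TRUE	FALSE	FALSE	per_drug_10
BMI	desvenlafaxine	weight_gain	345	0.013731925	0.18586603	1.0138266	0.70429442	1.459396	0.94110526	2.2433437e-05	-210.68179	-210.68451	TRUE	FALSE	FALSE	per_drug_10
BMI	duloxetine	weight_gain	273	0.24336518	0.21044477	1.2755343	0.84442531	1.9267398	0.24750428	0.0068605311	-172.63879	-173.31385	TRUE	FALSE	FALSE	per_drug_10
BMI	mirtazapine	weight_gain	308	0.10660886	0.19363023	1.112499	0.76116934	1.6259905	0.58192188	0.0013649083	-196.58183	-196.73351	TRUE	FALSE	FALSE	per_drug_10
BMI	amitriptyline	weight_gain	203	-0.18254716	0.25320169	0.83314535	0.50721852	1.3685052	0.47093688	0.0036856755	-121.19025	-121.45162	TRUE	FALSE	FALSE	per_drug_10
BMI	paroxetine	weight_gain	183	-0.18073098	0.23987912	0.83465987	0.52158376	1.3356572	0.45119444	0.0044240415	-110.83442	-111.11948	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	pooled	insomnia	1455	0.055735565	0.084106493	1.0573181	0.89663166	1.2468012	0.50753648	0.00041257191	-956.95717	-957.17683	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	sertraline	insomnia	829	0.10394271	0.13221899	1.1095369	0.85624243	1.4377612	0.43178511	0.0011374144	-441.91899	-442.22835	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	escitalopram	insomnia	647	0.19344648	0.14881634	1.2134244	0.90644205	1.6243718	0.19363496	0.0040146341	-340.28848	-341.1359	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	venlafaxine	insomnia	512	0.33820214	0.17289666	1.402424	0.99933115	1.9681093	0.050454059	0.012076705	-249.06797	-251.00718	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	fluoxetine	insomnia	448	0.20988886	0.17109884	1.233541	0.88209219	1.7250162	0.21993116	0.0050290656	-246.18891	-246.94261	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	citalopram	insomnia	397	0.0065176455	0.19606193	1.0065389	0.68539725	1.478151	0.97348098	4.3116901e-06	-205.87264	-205.87319	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	desvenlafaxine	insomnia	345	-0.04699669	0.1938615	0.95409056	0.65249079	1.3950983	0.8084516	0.00026373441	-179.23671	-179.26611	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	duloxetine	insomnia	273	0.11519378	0.24782064	1.1220909	0.69037128	1.8237837	0.64205518	0.0012993499	-127.88071	-127.98867	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	mirtazapine	insomnia	308	-0.22972238	0.24301245	0.79475421	0.49360582	1.2796329	0.34450004	0.0044960253	-160.53635	-160.98598	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	amitriptyline	insomnia	203	-0.073399082	0.27747511	0.92922992	0.53943105	1.6007018	0.79137547	0.00053941778	-103.62699	-103.66203	TRUE	FALSE	FALSE	per_drug_10
INSOMNIA	paroxetine	insomnia	183	0.2064864	0.34261535	1.229351	0.62811793	2.4060831	0.54672357	0.0033345984	-83.012064	-83.19445	TRUE	FALSE	FALSE	per_drug_10
HEADACHE	pooled	headache	1455	0.16820145	0.073312551	1.1831749	1.0248144	1.3660063	0.02177291	0.0049465233	-961.8597	-964.50734	TRUE	TRUE	FALSE	per_drug_10
HEADACHE	sertraline	headache	829	0.056570992	0.11627275	1.0582017	0.84255241	1.329046	0.6265865	0.00044295972	-429.23688	-429.35534	TRUE	FALSE	FALSE	per_drug_10
HEADACHE	escitalopram	headache	647	0.013574334	0.13133596	1.0136669	0.78361346	1.3112594	0.91768058	2.5848738e-05	-329.41728	-329.42262	TRUE	FALSE	FALSE	per_drug_10
HEADACHE	venlafaxine	headache	512	0.3338191	0.15877223	1.3962905	1.0228893	1.9060003	0.035509236	0.014340307	-239.32225	-241.57443	TRUE	TRUE	FALSE	per_drug_10
HEADACHE	fluoxetine	headache	448	0.26227311	0.16026391	1.2998815	0.9494823	1.7795928	0.1017334	0.0091169656	-240.96324	-242.31723	TRUE	FALSE	FALSE	per_drug_10
HEADACHE	citalopram	headache	397	0.39161959	0.17913013	1.4793748	1.0413636	2.1016194	0.028798812	0.018959457	-202.69341	-205.1328	TRUE	TRUE	FALSE	per_drug_10
HEADACHE	desvenlafaxine	headache	345	0.0655845	0.17394741	1.067783	0.75930924	1.5015759	0.70614658	0.00063364916	-181.73794	-181.80916	TRUE	FALSE	FALSE	per_drug_10
HEADACHE	duloxetine	headache	273	0.14463555	0.20160226	1.1556183	0.77841333	1.71561	0.47310871	0.0029460975	-139.19086	-139.44847	TRUE	FALSE	FALSE	per_drug_10
HEADACHE	mirtazapine	headache	308	0.22984113	0.19396039	1.2584001	0.86043754	1.840425	0.23602139	0.0069278748	-165.54003	-166.24606	TRUE	FALSE	FALSE	per_drug_10
HEADACHE	amitriptyline	headache	203	0.43863108	0.28247613	1.5505831	0.89135548	2.6973616	0.12046911	0.020293628	-88.956361	-90.176272	TRUE	FALSE	FALSE	per_drug_10
HEADACHE	paroxetine	headache	183	0.43585854	0.28028762	1.54629	0.89270857	2.6783801	0.11993647	0.022238045	-86.443554	-87.706776	TRUE	FALSE	FALSE	per_drug_10
MDD	pooled	suicidal_thoughts	1455	0.16261655	0.092919162	1.1765854	0.98068727	1.4116155	0.080103423	0.0030691519	-847.50805	-849.04747	TRUE	FALSE	FALSE	per_drug_10
MDD	sertraline	suicidal_thoughts	829	0.39192123	0.15942562	1.4798211	1.0826944	2.0226119	0.013958377	0.013140117	-343.63199	-346.73054	TRUE	TRUE	FALSE	per_drug_10
MDD	escitalopram	suicidal_thoughts	647	0.20570187	0.18226371	1.2283869	0.85939345	1.7558133	0.25906881	0.0034596105	-275.01085	-275.65332	TRUE	FALSE	FALSE	per_drug_10
MDD	venlafaxine	suicidal_thoughts	512	0.14532234	0.208452	1.1564123	0.76856043	1.7399924	0.48570885	0.0017790442	-196.82645	-197.07109	TRUE	FALSE	FALSE	per_drug_10
MDD	fluoxetine	suicidal_thoughts	448	0.41847625	0.2288465	1.5196442	0.97039249	2.3797779	0.067454621	0.014535065	-165.67558	-167.39592	TRUE	FALSE	FALSE	per_drug_10
MDD	citalopram	suicidal_thoughts	397	0.18471154	0.22763612	1.2028714	0.76993664	1.8792451	0.41711685	0.0029838329	-162.46934	-162.80108	TRUE	FALSE	FALSE	per_drug_10
MDD	desvenlafaxine	suicidal_thoughts	345	0.64561589	0.27215621	1.9071613	1.1187361	3.2512263	0.017681296	0.032600326	-121.22447	-124.13411	TRUE	TRUE	FALSE	per_drug_10
MDD	duloxetine	suicidal_thoughts	273	0.11157151	0.2930542	1.1180337	0.62951591	1.9856517	0.70341124	0.00096888993	-108.29282	-108.3653	TRUE	FALSE	FALSE	per_drug_10
MDD	mirtazapine	suicidal_thoughts	308	-0.23885549	0.26177556	0.78752868	0.47145758	1.3154979	0.36153515	0.0047864897	-127.78495	-128.20201	TRUE	FALSE	FALSE	per_drug_10
MDD	amitriptyline	suicidal_thoughts	203	0.12116789	0.40127865	1.1288144	0.51410702	2.478515	0.76268676	0.00097200285	-63.366407	-63.412255	TRUE	FALSE	FALSE	per_drug_10
MDD	paroxetine	suicidal_thoughts	183	-0.11968407	0.45307485	0.88720068	0.36505967	2.1561545	0.79165694	0.00075706254	-64.33944	-64.374441	TRUE	FALSE	FALSE	per_drug_10
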