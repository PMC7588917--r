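# Published per-gene adaptation indices and two-condition microarray signals
# (log2, glucose vs ball-milled aspen) for the Ceriporiopsis subvermispora
# lignocellulolytic gene set, as printed; used as worked-example input.
category	transcript_id	cai	aatai	tai	cpb	nc	z_cai	z_aatai	z_cpb	z_tai	putative_function	log2_glucose	log2_bma	ratio	p_value
lignin_peroxidase	49863	0.814	0.720	0.371	0.028	40.95	1.236	1.848	0.136	1.513	Peroxidase, MnP	9.58	11.15	2.970	0.08320
lignin_peroxidase	50297	0.822	0.735	0.384	0.055	41.46	1.394	2.321	1.565	2.111	Peroxidase, MnP	13.13	11.88	0.421	0.19000
lignin_peroxidase	50686	0.823	0.728	0.379	0.051	41.50	1.414	2.100	1.387	1.901	Peroxidase, MnP	9.35	9.42	1.048	0.45600
lignin_peroxidase	106380	0.815	0.716	0.371	0.039	38.67	1.255	1.722	0.705	1.536	Peroxidase, MnP	8.93	8.93	1.000	0.99900
lignin_peroxidase	111364	0.770	0.689	0.357	0.015	50.57	0.364	0.872	-0.611	0.929	Peroxidase, VP-like	9.18	9.11	0.957	0.52800
lignin_peroxidase	117521	0.819	0.722	0.367	0.042	40.88	1.335	1.911	0.876	1.340	Peroxidase, MnP	9.57	9.49	0.945	0.30600
lignin_peroxidase	124144	0.696	0.653	0.321	0.031	61.00	-1.101	-0.261	0.284	-0.660	Peroxidase, generic	11.30	11.21	0.942	0.29300
lignin_peroxidase	126018	0.828	0.721	0.366	0.030	40.55	1.513	1.880	0.230	1.314	Peroxidase, MnP	9.69	9.50	0.874	0.10000
lignin_peroxidase	126058	0.788	0.673	0.344	0.026	44.68	0.721	0.368	-0.015	0.340	Peroxidase, MnP	9.94	9.44	0.707	0.00595
lignin_peroxidase	128590	0.824	0.724	0.367	0.052	41.12	1.434	1.974	1.409	1.352	Peroxidase, MnP	9.78	9.52	0.837	0.01960
lignin_peroxidase	129418	0.767	0.709	0.373	0.044	49.06	0.305	1.502	1.011	1.619	Peroxidase, MnP	10.22	12.92	6.508	0.00895
lignin_peroxidase	130659	0.781	0.721	0.368	0.022	50.53	0.582	1.880	-0.220	1.396	Peroxidase, LiP-like	10.88	10.30	0.673	0.03900
lignin_peroxidase	136058	0.770	0.688	0.352	0.029	50.91	0.364	0.841	0.167	0.683	Peroxidase, MnP	10.16	10.76	1.519	0.16700
lignin_peroxidase	151947	0.831	0.729	0.373	0.052	40.42	1.572	2.132	1.410	1.600	Peroxidase, MnP	9.00	8.93	0.955	0.24200
lignin_peroxidase	155372	0.797	0.711	0.369	0.040	42.88	0.899	1.565	0.765	1.443	Peroxidase, MnP	8.86	8.84	0.988	0.74100
lignin_peroxidase	169968	0.816	0.718	0.369	0.032	42.96	1.275	1.785	0.359	1.434	Peroxidase, MnP	10.27	10.16	0.930	0.44200
laccase	84170	0.741	0.664	0.325	0.032	58.64	-0.210	0.085	0.338	-0.517	Laccase	10.45	10.34	0.931	0.17000
laccase	88089	0.841	0.684	0.336	0.039	41.00	1.770	0.715	0.695	-0.016	Laccase	9.38	9.29	0.939	0.17800
laccase	120834	0.737	0.669	0.330	0.011	57.80	-0.289	0.242	-0.825	-0.271	Laccase	10.74	10.66	0.945	0.50800
laccase	127045	0.752	0.681	0.339	0.024	54.32	0.008	0.620	-0.103	0.112	Laccase	10.54	10.02	0.694	0.00260
laccase	127050	0.721	0.667	0.334	0.015	60.26	-0.606	0.179	-0.581	-0.098	Laccase	11.35	11.19	0.895	0.54300
laccase	130783	0.791	0.705	0.347	0.037	43.13	0.780	1.376	0.605	0.461	Laccase	11.02	13.77	6.766	0.00426
laccase	149668	0.775	0.679	0.334	0.019	51.25	0.463	0.557	-0.397	-0.120	Laccase	9.91	9.81	0.931	0.35300
cellulose_binding	59733	0.812	0.704	0.346	0.026	46.11	1.196	1.344	-0.018	0.414	GH10-CBM1	9.24	13.69	21.783	0.00004
cellulose_binding	66688	0.824	0.716	0.347	0.025	47.02	1.434	1.722	-0.048	0.488	GH61-CBM1	9.62	14.87	37.901	0.00002
cellulose_binding	67561	0.853	0.730	0.366	0.020	39.43	2.008	2.163	-0.336	1.313	GH10-CBM1	10.30	13.71	10.642	0.00002
cellulose_binding	68569	0.837	0.735	0.345	0.024	43.59	1.691	2.321	-0.095	0.383	CE1-CBM1	9.80	13.10	9.858	0.00023
cellulose_binding	79557	0.802	0.715	0.345	0.022	42.15	0.998	1.691	-0.231	0.373	GH5-CBM1	10.24	14.04	13.874	0.00001
cellulose_binding	87580	0.783	0.693	0.321	0.010	49.31	0.622	0.998	-0.884	-0.692	CE16-CBM1	10.94	14.46	11.540	0.00004
cellulose_binding	89533	0.838	0.736	0.353	0.052	42.06	1.711	2.352	1.426	0.719	GH61-CBM1	10.35	13.56	9.306	0.00002
cellulose_binding	89534	0.870	0.731	0.352	0.044	37.58	2.345	2.195	0.980	0.693	GH61-CBM1	9.42	10.13	1.637	0.02300
cellulose_binding	101925	0.845	0.723	0.359	0.033	38.22	1.850	1.943	0.394	1.020	GH7-CBM1	8.84	8.96	1.086	0.09060
cellulose_binding	106777	0.804	0.712	0.348	0.035	49.87	1.038	1.596	0.511	0.500	GH5-CBM1	9.54	14.35	28.050	0.00001
cellulose_binding	109840	0.857	0.741	0.370	0.039	38.16	2.087	2.509	0.733	1.471	GH10-CBM1	9.52	11.85	5.009	0.00053
cellulose_binding	129028	0.852	0.733	0.363	0.042	39.91	1.988	2.258	0.849	1.181	GH5-CBM1	9.81	10.79	1.985	0.01830
cellulose_binding	133809	0.865	0.713	0.338	0.040	37.08	2.246	1.628	0.779	0.091	GH11-CBM1	10.86	11.42	1.466	0.02090
cellulose_binding	148588	0.856	0.742	0.376	0.008	34.45	2.067	2.541	-0.967	1.756	GH7-CBM1	11.02	12.62	3.015	0.00018
cdh	84792	0.803	0.688	0.338	0.023	48.09	1.018	0.841	-0.137	0.071	CDH	9.29	13.76	22.241	0.00002
cdh	87110	0.769	0.679	0.332	0.024	50.71	0.345	0.557	-0.111	-0.189	CDH	11.31	11.04	0.827	0.20200
cdh	125610	0.762	0.665	0.318	0.044	53.34	0.206	0.116	0.981	-0.814	cir1 CBM1	10.17	10.40	1.170	0.23300
cdh	147544	0.712	0.665	0.318	0.025	56.98	-0.784	0.116	-0.060	-0.798	CDH	11.24	11.02	0.860	0.19900
delta12_dehydrogenase	58880	0.727	0.670	0.317	0.008	59.40	-0.487	0.274	-0.973	-0.853	Delta-12 FAD	10.36	10.29	0.956	0.72900
delta12_dehydrogenase	121074	0.731	0.644	0.313	0.022	55.49	-0.408	-0.545	-0.219	-1.033	Delta-12 FAD	10.58	10.23	0.783	0.01490
delta12_dehydrogenase	124050	0.856	0.736	0.368	0.042	38.22	2.067	2.352	0.875	1.416	Delta-12 FAD, Cs-fad2	12.74	12.66	0.941	0.65300
delta12_dehydrogenase	136101	0.714	0.649	0.310	0.007	56.78	-0.745	-0.387	-1.016	-1.178	Delta-12 FAD	11.01	12.54	2.895	0.00022
delta12_dehydrogenase	167690	0.736	0.670	0.325	0.013	58.45	-0.309	0.274	-0.706	-0.484	Delta-12 FAD	10.67	10.11	0.678	0.00870
delta9_dehydrogenase	87875	0.810	0.694	0.343	0.035	44.18	1.156	1.030	0.475	0.313	Delta-9 FAD, Cs-ole1	8.93	8.94	1.006	0.88000
delta9_dehydrogenase	129045	0.728	0.679	0.335	0.045	56.92	-0.467	0.557	1.017	-0.075	Delta-9 FAD, Cs-ole1	8.95	8.91	0.974	0.52700
delta9_dehydrogenase	129048	0.848	0.740	0.366	0.050	41.46	1.909	2.478	1.291	1.292	Delta-9 FAD, Cs-ole1	11.78	12.35	1.478	0.02980
delta9_dehydrogenase	133675	0.760	0.669	0.330	0.024	54.62	0.166	0.242	-0.113	-0.266	Delta-9 FAD, Cs-ole1	9.64	9.51	0.917	0.17900
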