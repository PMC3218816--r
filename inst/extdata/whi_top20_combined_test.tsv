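rank	snp_id	chromosome	position	maf	alleles	p_combined	fdr_published	p_main	rank_main	gene
1	rs1219648	10q26	123336180	0.42	G/A	6.45e-09	3.21e-05	3.90e-10	1	FGFR2
2	rs2981579	10q26	123327325	0.44	A/G	7.76e-09	1.94e-05	2.78e-09	2	FGFR2
3	rs3750817	10q26	123322567	0.37	T/C	5.61e-08	9.32e-05	9.02e-08	5	FGFR2
4	rs11200014	10q26	123324920	0.41	A/G	1.08e-07	0.000135	3.40e-09	3	FGFR2
5	rs2420946	10q26	123341314	0.42	T/C	1.56e-07	0.000156	1.49e-08	4	FGFR2
6	rs2981582	10q26	123342307	0.41	A/G	5.25e-07	0.000437	9.99e-08	6	FGFR2
7	rs7705343	5p12	44915334	0.42	G/A	5.88e-05	0.0419	0.000355	11	MRPS30
8	rs13159598	5p12	44841683	0.42	G/A	0.000136	0.0846	0.000425	13	MRPS30
9	rs11746980	5p12	44935642	0.43	C/T	0.000240	0.133	0.000511	16	MRPS30
10	rs9790879	5p12	44813635	0.43	A/G	0.000244	0.122	0.000963	19	MRPS30
11	rs2330572	5p12	44776746	0.43	C/A	0.000294	0.133	0.00129	22	MRPS30
12	rs7555040	1p33	47641903	0.13	G/A	0.000336	0.140	0.002483	26	Unknown
13	rs4415084	5p12	44698272	0.43	T/C	0.000400	0.153	0.000436	14	MRPS30
14	rs994793	5p12	44779004	0.43	G/A	0.000417	0.148	0.00184	23	MRPS30
15	rs2218080	5p12	44750087	0.44	C/T	0.000446	0.148	0.00274	30	MRPS30
16	rs7795554	7p21	12159269	0.36	C/T	0.000498	0.155	0.00353	40	Unknown
17	rs7519783	1q32	198951680	0.27	G/A	0.000904	0.265	0.229	1160	Unknown
18	rs1499111	4q28	129691789	0.22	T/C	0.00115	0.318	0.0736	431	Unknown
19	rs719278	3q11	98887302	0.40	A/G	0.00122	0.320	0.238	1204	EPHA6
20	rs1232355	3q26	88073313	0.05	C/T	0.00132	0.329	0.179	942	Unknown
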