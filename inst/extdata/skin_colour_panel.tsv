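rsid	chrom	position_grch38	locus	allele1	allele2	effect_allele	variant_class	tier	rank	assoc_r2	assoc_p	glm_coefficient	synonyms
rs6679651	1	149757453	HIST2H2BF	C	T	T	SNV	candidate	.	.	.	.	.
rs12233134	2	25106146	EFR3B	C	T	T	SNV	candidate	.	.	.	.	.
rs40132	5	33950597	SLC45A2	A	G	G	SNV	candidate	.	.	.	.	.
rs16891982	5	33951587	SLC45A2	C	G	G	SNV	final	5	0.142	8.13e-58	0.27912209	.
rs2287949	5	33954405	SLC45A2	C	T	T	SNV	associated	.	0.006	0.004	.	.
rs28777	5	33958853	SLC45A2	G	T	T	SNV	final	24	0.097	3.14e-40	0.0865	.
rs26722	5	33963764	SLC45A2	A	G	G	SNV	candidate	.	.	.	.	.
rs6867641	5	33985751	SLC45A2	C	T	T	SNV	candidate	.	.	.	.	.
rs13289	5	33986303	SLC45A2	C	G	G	SNV	associated	.	0.0114	5.8e-05	.	.
rs1936208	6	139644247	Intergenic between ATP5F1P6 and LOC100129554	C	T	T	SNV	candidate	.	.	.	.	.
rs12203592	6	396320	IRF4	C	T	T	SNV	final	2	0.0201	5.18e-09	-0.17565966	.
rs4959270	6	457747	LOC105374875	A	C	C	SNV	candidate	.	.	.	.	.
rs477823	7	63287722	<NA>	G	T	T	SNV	associated	.	0.0068	0.001	.	.
rs1385229	8	95759318	C8orf37-AS1	A	G	G	SNV	candidate	.	.	.	.	.
rs10756819	9	16858085	BNC2	A	G	G	SNV	final	36	0.021	2.48e-09	0.00132	.
rs683	9	12709304	TYRP1	A	C	C	SNV	final	32	0.0096	4.6e-05	0.017	.
rs3763971	10	8061334	GATA3	A	G	G	SNV	candidate	.	.	.	.	.
rs10443915	10	52060818	PRKG1	A	T	T	SNV	candidate	.	.	.	.	.
rs12765852	10	52061566	PRKG1	C	T	T	SNV	candidate	.	.	.	.	.
rs10831496	11	88824822	GRM5	A	G	G	SNV	candidate	.	.	.	.	.
rs4936890	11	124044034	Intergenic between OR10G7 and OR10D5P	A	G	G	SNV	associated	.	0.0113	1.5e-05	.	.
rs35264875	11	69078930	TPCN2	A	T	T	SNV	associated	.	0.0034	0.016	.	.
rs1042602	11	89178527	TYR	A	C	C	SNV	final	12	0.0025	0.04	-0.06223707	.
rs1393350	11	89277877	TYR	A	G	G	SNV	final	21	0.0109	1.8e-05	-0.056	.
rs1126809	11	89284793	TYR	A	G	G	SNV	final	19	0.015	2.2e-06	-0.0835771	.
rs642742	12	88905968	KITLG	A	G	G	SNV	associated	.	0.0533	5.2e-21	.	.
rs12821256	12	88934557	KITLG	C	T	T	SNV	final	33	0.0024	0.046	-0.0152	.
rs3782974	13	94440641	DCT	A	T	T	SNV	associated	.	0.0095	6.6e-05	.	.
rs2050537	13	96608646	HS6ST3	C	T	T	SNV	candidate	.	.	.	.	.
rs4983161	14	19726716	<NA>	A	T	T	SNV	associated	.	0.007	0.001	.	.
rs12896399	14	92307318	SLC24A4	G	T	T	SNV	final	29	0.011	1.8e-05	-0.0255	.
rs2402130	14	92334858	SLC24A4	A	G	G	SNV	final	27	0.027	6.8e-12	0.0398	.
rs17128291	14	92416481	SLC24A4	A	G	G	SNV	final	28	0.0147	7.28e-07	-0.0391	.
rs12914268	15	22150292	<NA>	A	G	G	SNV	candidate	.	.	.	.	.
rs1129038	15	28111712	HERC2	A	G	G	SNV	final	17	0.092	1.77e-37	0.10536412	.
rs12913832	15	28120471	HERC2	A	G	G	SNV	final	20	0.091	9.9e-37	0.0812	.
rs2238289	15	28208068	HERC2	C	T	T	SNV	final	15	0.033	5.24e-14	-0.11378297	.
rs8182028	15	28222788	HERC2	C	T	T	SNV	candidate	.	.	.	.	.
rs3940272	15	28223576	HERC2	A	C	C	SNV	candidate	.	.	.	.	.
rs6497292	15	28251048	HERC2	A	G	G	SNV	final	30	0.075	2.29e-30	0.0579	.
rs16950941	15	28257597	HERC2	A	G	G	SNV	candidate	.	.	.	.	.
rs1667394	15	28285035	HERC2	A	G	G	SNV	final	6	0.052	1.15e-21	0.16017374	.
rs1473917	15	22067210	LOC101927079	C	T	T	SNV	candidate	.	.	.	.	.
rs1545397	15	27942625	OCA2	A	T	T	SNV	final	34	0.0166	2.27e-07	-0.0103	.
rs1800414	15	27951890	OCA2	A	G	G	SNV	final	4	0.047	2.79e-19	-0.53990294	.
rs1800407	15	27985171	OCA2	A	G	G	SNV	final	8	0.007	0.00044	-0.19827349	.
rs1800401	15	28014906	OCA2	C	T	T	SNV	associated	.	0.0054	0.005	.	.
rs12441727	15	28026628	OCA2	A	G	G	SNV	final	25	0.0047	0.005	0.0603	.
rs1448485	15	28037594	OCA2	A	C	C	SNV	candidate	.	.	.	.	.
rs16950821	15	28038360	OCA2	A	G	G	SNV	associated	.	0.037	3.6e-15	.	.
rs1470608	15	28042974	OCA2	A	C	C	SNV	final	31	0.063	1.04e-25	-0.0379	.
rs7495174	15	28099091	OCA2	A	G	G	SNV	candidate	.	.	.	.	.
rs1426654	15	48134286	SLC24A5	A	G	G	SNV	final	1	0.15	1.19e-59	0.52412661	.
rs11076649	16	89992927	AFG3L1P	C	G	G	SNV	associated	.	0.0058	0.002	.	.
rs3114908	16	89317316	ANKRD11	A	G	G	SNV	final	35	0.0201	9.8e-09	0.00393	.
rs8049897	16	89957793	DEF8	A	G	G	SNV	associated	.	0.022	1.5e-09	.	.
rs8051733	16	89957797	DEF8	A	G	G	SNV	final	16	0.029	2.7e-12	-0.06364481	.
rs164741	16	89625889	DPEP1	C	T	T	SNV	associated	.	0.015	2.76e-07	.	.
rs2239359	16	89783071	FANCA	C	T	T	SNV	candidate	.	.	.	.	.
rs3212355	16	89917969	MC1R	C	T	T	SNV	final	22	0.0206	2.89e-08	0.2	.
rs312262906	16	89919341	MC1R	-	insA	insA	indel	associated	.	0.0085	0.00012	.	N29insA
rs1805005	16	89919435	MC1R	G	T	T	SNV	candidate	.	.	.	.	.
rs1805006	16	89919509	MC1R	A	C	C	SNV	final	13	0.003	0.022	-0.31065309	.
rs2228479	16	89919531	MC1R	A	G	G	SNV	final	11	0.019	7.45e-09	-0.1091518	rs228479
rs11547464	16	89919682	MC1R	A	G	G	SNV	final	9	0.0071	0.00046	-0.296	.
rs1805007	16	89919708	MC1R	C	T	T	SNV	final	3	0.0268	1.28e-11	-0.28231475	.
rs201326893	16	89919713	MC1R	C	A	A	SNV	candidate	.	.	.	.	Y152OCH
rs1110400	16	89919721	MC1R	C	T	T	SNV	final	18	0.0037	0.011	-0.20059956	.
rs1805008	16	89919735	MC1R	C	T	T	SNV	final	7	0.021	9.2e-10	-0.19994906	.
rs885479	16	89919746	MC1R	A	G	G	SNV	final	10	0.0326	7.63e-14	-0.16300889	.
rs1805009	16	89920137	TUBB3	C	G	G	SNV	candidate	.	.	.	.	.
rs333113	17	4497060	SPNS2	C	G	G	SNV	associated	.	0.013	2.41e-06	.	.
rs6119471	20	34197405	ASIP	C	G	G	SNV	final	26	0.214	4.76e-85	0.0927	.
rs2424984	20	34262568	ASIP	C	T	T	SNV	associated	.	0.044	2.06e-17	.	.
rs1885120	20	34989185	MYH7B	C	G	G	SNV	associated	.	0.003	0.039	.	.
rs2378249	20	34630285	PIGU	A	G	G	SNV	final	23	0.008	0.00014	-0.0476	.
rs6059655	20	34077941	RALY	A	G	G	SNV	final	14	0.008	0.00042	-0.11371271	.
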