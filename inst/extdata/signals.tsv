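signal_id	compound_id	center	window_lo	window_hi	n_protons	multiplicity	role	corrections	derived	assumed_n	center2	window2_lo	window2_hi	window_early_lo	window_early_hi	provenance	lod_override
tg_ref	TG	4.14	4.10	4.18	4	ddd	reference	pet_423,ho_ko_423	FALSE	FALSE	4.30	4.26	4.34	NA	NA	reported; sn-1/sn-3 glyceryl CH2, two multiplets summed; late-oxidation carbinol interlopers near 4.23 ppm listed for subtraction if window overrides include them	NA
L_bisallylic	L	2.77	2.75	2.80	2	t	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported; bis-allylic CH2 (signal G), 2H per intact linoleic chain	NA
gT_aromatic	gT	6.360	6.350	6.370	1	s	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; window assumed	NA
STN_c18	STN	0.651	0.6465	0.6555	3	s	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; C18 methyl 3H; window assumed	NA
d7A_c18	d7A	0.540	0.535	0.545	3	s	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; C18 methyl 3H; window assumed	NA
mhpo_ze_655	mHPO_cZE_dE	6.55	6.53	6.57	1	m	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; conjugated olefinic proton	NA
mhpo_ee_624	mHPO_cEE_dE	6.24	6.22	6.26	1	m	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; conjugated olefinic proton	NA
mhpo_ze_ooh	mHPO_cZE_dE	8.42	8.405	8.435	1	s	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported region 8.38-8.52; OOH proton, exact center assumed	NA
mhpo_ee_ooh	mHPO_cEE_dE	8.46	8.445	8.475	1	s	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported region 8.38-8.52; OOH proton, exact center assumed	NA
total_ooh	total_OOH	8.80	8.30	9.30	1	br	quantifier	ald_23epo_901	TRUE	FALSE	NA	NA	NA	8.38	8.52	reported windows; derived channel integrating all OOH protons; early narrow window used before other OOH carriers appear	NA
dhpo_482	dHPO_nc_dE	4.82	4.795	4.845	1	dd	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; methine carbinol proton	NA
dhpo_ooh	dHPO_nc_dE	8.85	8.80	8.90	2	br	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	assumed center within reported broad 8.3-9.3 OOH region; 2 OOH protons	NA
hpo_epo_585	HPO_EPO_mE	5.85	5.83	5.87	1	dd	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; olefinic proton alpha to C-OOH	NA
hpo_epo_ooh	HPO_EPO_mE	8.70	8.685	8.715	1	br	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported region 8.6-8.8; OOH proton, exact center assumed	NA
hpo_epo_311	HPO_EPO_mE	3.11	3.095	3.125	1	m	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; epoxydic proton	NA
mho_648	mHO_cZE_dE	6.48	6.465	6.495	1	m	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; conjugated olefinic proton	NA
ho_epo1_594	HO_EPO_mE_1	5.945	5.925	5.965	1	dd	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported 5.94-5.95; olefinic proton alpha to C-OH	NA
ho_epo1_341	HO_EPO_mE_1	3.41	3.395	3.425	1	dd	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; co-resonant with dihydroxy methine carbinol region	NA
ho_epo2_396	HO_EPO_mE_2	3.96	3.949	3.971	1	q	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; threo methine carbinol; window kept clear of 3.98 ppm group	NA
ho_epo2_293	HO_EPO_mE_2	2.93	2.915	2.945	1	dt	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; epoxydic proton inside Z-epoxide window	NA
ho_ko_324	HO_KO_mE	3.24	3.228	3.252	1	t	quantifier		FALSE	TRUE	NA	NA	NA	NA	NA	reported center; composite methylenic signal, proton count not stated, n assumed 1	NA
ho_ko_423	HO_KO_mE	4.23	4.21	4.25	1	dd	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; methine carbinol near the reference region	NA
mko_ze_749	mKO_cZE_dE	7.49	7.482	7.510	1	m	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; window narrowed away from adjacent furanone signal	NA
mko_ee_713	mKO_cEE_dE	7.13	7.115	7.145	1	m	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center	NA
ko_epo_ee_638	KO_EPO_mE_EE	6.38	6.372	6.392	1	d	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center	NA
ko_epo_ee_291	KO_EPO_mE_EE	2.91	2.895	2.925	1	td	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; epoxydic proton inside Z-epoxide window	NA
ko_epo_ee_320	KO_EPO_mE_EE	3.20	3.188	3.212	1	dd	qualifier		FALSE	TRUE	NA	NA	NA	NA	NA	reported center; composite E,E+Z,E signal, attributed here to the E,E channel	NA
ko_epo_ze_666	KO_EPO_mE_ZE	6.66	6.64	6.68	1	dd	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center	NA
ko_epo_ze_352	KO_EPO_mE_ZE	3.52	3.508	3.532	1	dd	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center	NA
ko_epo_vic_702	KO_EPO_mE_vic	7.02	7.005	7.035	1	dt	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center	NA
ekh_242	EPO_KO_HO	2.42	2.405	2.435	1	dd	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; least-overlapped channel of this structure	NA
ekh_316	EPO_KO_HO	3.16	3.148	3.172	1	d	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center	NA
zepo_292	Z_EPO_Z_mE	2.92	2.88	2.98	2	m	quantifier	ho_epo2_293,ko_epo_ee_291	FALSE	FALSE	NA	NA	NA	NA	NA	reported window 2.88-2.98; epoxydic protons; co-resonant hydroxy- and keto-epoxide contributions subtracted	0.4
eepo_270	E_EPO_Z_mE	2.70	2.66	2.73	2	m	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported window 2.66-2.73; epoxydic protons; assumed sole occupant	0.8
depo_173	dEPO	1.73	1.715	1.745	1	m	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported standard signal; absence channel, never expected above LOD	NA
dho_342	dHO_pHO	3.42	3.38	3.46	1	br	quantifier	ho_epo1_341	FALSE	TRUE	NA	NA	NA	NA	NA	reported center; broad methine carbinol band; n per structure ambiguous, assumed 1	NA
carb_398	carbinol_398	3.985	3.973	3.997	1	m	quantifier		FALSE	TRUE	NA	NA	NA	NA	NA	reported near 3.98; separated from the 3.96 threo carbinol channel	NA
pet_362	poly_ethers	3.62	3.605	3.635	1	m	quantifier		FALSE	TRUE	NA	NA	NA	NA	NA	reported center; ether/alcohol methine protons	NA
pet_423	poly_ethers	4.23	4.21	4.25	1	m	qualifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; interloper flanked by the reference sub-windows	NA
pf_810	poly_formates	8.10	8.03	8.17	1	br	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported window 8.03-8.17; formate H	NA
formic_801	formic_acid	8.01	8.000	8.020	1	s	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center	NA
furan_727	alkyl_furans	7.27	7.255	7.285	1	dd	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center	NA
furanone_747	furanone_5p	7.47	7.452	7.480	1	dd	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; window narrowed away from adjacent keto-diene signal	NA
ald_2e_949	ald_2E_alkenals	9.49	9.475	9.505	1	d	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; CHO proton	NA
ald_24ee_953	ald_24EE_alkadienals	9.53	9.515	9.545	1	d	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; CHO proton	NA
ald_4ho_957	ald_4HO_2E_alkenals	9.57	9.555	9.585	1	d	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; CHO proton	NA
ald_4hpo_961	ald_4HPO_2E_alkenals	9.61	9.595	9.625	1	d	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	assumed center in CHO region	NA
ald_45epo_966	ald_45EPO_2E_alkenals	9.66	9.645	9.675	1	d	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	assumed center in CHO region	NA
ald_4oxo_971	ald_4oxo_2E_alkenals	9.71	9.695	9.725	1	d	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	assumed center in CHO region	NA
ald_nalk_976	ald_nalkanals	9.76	9.745	9.775	1	t	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; CHO proton	NA
ald_23epo_901	ald_23EPO_alkanals	9.01	8.995	9.025	1	d	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	assumed center; epoxyaldehyde CHO, inside the broad OOH window hence subtracted there	NA
sterol_5a6a_061	epoxysterol_5a6a	0.61	0.605	0.615	3	s	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; C18 methyl 3H	NA
sterol_5b6b_064	epoxysterol_5b6b	0.64	0.635	0.645	3	s	quantifier		FALSE	FALSE	NA	NA	NA	NA	NA	reported center; C18 methyl 3H	NA
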