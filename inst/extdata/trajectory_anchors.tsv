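compound_id	day	conc	status
Ln	0	18.8	reported
Ln	8	14	assumed
Ln	11	0.05	assumed
Ln	16	0	assumed
L	0	1461.6	reported
L	8	1400.8	derived
L	11	1314.1	derived
L	14	544.0	derived
L	16	291.2	reported
O	0	990.2	reported
O	8	950	assumed
O	11	900	assumed
O	14	850	assumed
O	16	820	assumed
S	0	529.4	reported
S	16	520	assumed
gT	0	1.4	reported
gT	2	1.32	derived
gT	11	0.06	derived
gT	12	0	assumed
gT	16	0	assumed
STN	0	0.7	assumed
STN	9	0.65	assumed
STN	13	0.45	assumed
STN	16	0.3	assumed
d7A	0	0.5	assumed
d7A	9	0.45	assumed
d7A	13	0.15	assumed
d7A	14	0.02	assumed
d7A	16	0	assumed
mHPO_cZE_dE	4	1.0	assumed
mHPO_cZE_dE	8	14.2	derived
mHPO_cZE_dE	11	28.3	derived
mHPO_cZE_dE	13	48.5	reported
mHPO_cZE_dE	16	12.3	reported
mHPO_cEE_dE	4	1.0	assumed
mHPO_cEE_dE	8	16.6	derived
mHPO_cEE_dE	11	61.9	derived
mHPO_cEE_dE	13	140.9	reported
mHPO_cEE_dE	16	37.9	reported
dHPO_nc_dE	9	0.3	assumed
dHPO_nc_dE	13	19.2	reported
dHPO_nc_dE	16	10	assumed
HPO_EPO_mE	10	0.4	assumed
HPO_EPO_mE	14	38.7	reported
HPO_EPO_mE	16	24.2	reported
mHO_cZE_dE	8	0.3	assumed
mHO_cZE_dE	10	1.2	assumed
mHO_cZE_dE	12	0.8	assumed
mHO_cZE_dE	13	0.05	assumed
mHO_cZE_dE	16	0	assumed
HO_EPO_mE_1	13	0.3	assumed
HO_EPO_mE_1	14	4.8	reported
HO_EPO_mE_1	16	4.0	assumed
HO_EPO_mE_2	13	0.2	assumed
HO_EPO_mE_2	16	3.7	reported
HO_KO_mE	14	1.0	assumed
HO_KO_mE	16	1.8	assumed
mKO_cZE_dE	12	1.0	assumed
mKO_cZE_dE	13	5.0	reported
mKO_cZE_dE	16	4.0	assumed
mKO_cEE_dE	11	0.8	assumed
mKO_cEE_dE	15	11.2	reported
mKO_cEE_dE	16	10.5	assumed
KO_EPO_mE_EE	14	1.5	assumed
KO_EPO_mE_EE	16	6.0	assumed
KO_EPO_mE_ZE	14	0.5	assumed
KO_EPO_mE_ZE	16	2.5	assumed
KO_EPO_mE_vic	14	0.3	assumed
KO_EPO_mE_vic	16	1.2	assumed
EPO_KO_HO	12	0.2	assumed
EPO_KO_HO	16	1.0	assumed
Z_EPO_Z_mE	13	0.5	assumed
Z_EPO_Z_mE	16	27.3	reported
E_EPO_Z_mE	13	0.4	assumed
E_EPO_Z_mE	16	17.0	reported
dHO_pHO	12	0.5	assumed
dHO_pHO	16	8.0	assumed
carbinol_398	12	0.4	assumed
carbinol_398	16	15.0	assumed
poly_ethers	13	0.5	assumed
poly_ethers	16	12.0	assumed
poly_formates	13	0.4	assumed
poly_formates	16	12.0	assumed
formic_acid	12	0.3	assumed
formic_acid	16	6.0	assumed
alkyl_furans	14	0.5	assumed
alkyl_furans	16	3.5	assumed
furanone_5p	13	0.3	assumed
furanone_5p	16	3.0	assumed
ald_2E_alkenals	11	0.3	assumed
ald_2E_alkenals	16	15.6	reported
ald_4HPO_2E_alkenals	11	0.2	assumed
ald_4HPO_2E_alkenals	15	9.0	assumed
ald_4HPO_2E_alkenals	16	8.0	assumed
ald_nalkanals	12	0.3	assumed
ald_nalkanals	16	7.0	assumed
ald_24EE_alkadienals	12	0.3	assumed
ald_24EE_alkadienals	16	6.5	assumed
ald_4HO_2E_alkenals	13	0.5	assumed
ald_4HO_2E_alkenals	16	19.8	reported
ald_4oxo_2E_alkenals	13	0.2	assumed
ald_4oxo_2E_alkenals	16	4.0	assumed
ald_45EPO_2E_alkenals	13	0.3	assumed
ald_45EPO_2E_alkenals	16	6.0	assumed
ald_23EPO_alkanals	15	0.3	assumed
ald_23EPO_alkanals	16	2.1	assumed
epoxysterol_5a6a	14	0.12	assumed
epoxysterol_5a6a	16	0.18	reported
epoxysterol_5b6b	14	0.11	assumed
epoxysterol_5b6b	16	0.14	reported
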