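compound_id	name	category	first_detected_day	notes
TG	triglyceride glyceryl backbone	acyl	0	internal reference; sn-1/sn-3 CH2 protons; never tabulated in concentration tables (1 mol TG per mol TG)
Ln	linolenic acyl groups	acyl	0	omega-3 diunsaturated+; minor in corn oil; bis-allylic signal fully overlapped by linoleic, no clean channel
L	linoleic acyl groups	acyl	0	main unsaturated acyl group; tracked via bis-allylic CH2 signal G
O	oleic acyl groups	acyl	0	mono-unsaturated; no clean isolated 1H channel, determined only compositionally
S	saturated acyl groups	acyl	0	no clean isolated 1H channel, determined only compositionally
gT	gamma-tocopherol	minor_component	0	main detectable tocopherol; aromatic singlet; two-stage degradation, gone by day 12
STN	sitostanol	minor_component	0	C18 methyl singlet; most oxidation-stable minor component, persists to day 16
d7A	delta7-avenasterol	minor_component	0	C18 methyl singlet; degrades faster than sitostanol, gone after day 13
mHPO_cZE_dE	monohydroperoxy-conjugated Z,E-dienes	primary_oxidation	4	9-/13-OOH Z,E conjugated dienes from linoleate; intermediate, maximum near day 13
mHPO_cEE_dE	monohydroperoxy-conjugated E,E-dienes	primary_oxidation	4	9-/13-OOH E,E conjugated dienes from linoleate; intermediate, maximum near day 13
total_OOH	total hydroperoxy groups	primary_oxidation	4	derived channel: all OOH protons; equals sum of mHPO-c-dEs until other OOH carriers appear (day 9)
dHPO_nc_dE	dihydroperoxy-non-conjugated dienes	secondary_oxidation	9	9,12-/10,13-dihydroperoxy E,E dienes; methine carbinol dd channel; maximum day 13
HPO_EPO_mE	hydroperoxy-epoxy-monoenes	secondary_oxidation	10	e.g. 9-OOH-12,13-E-epoxy-10E-octadecenoate; olefinic dd channel; maximum day 14
mHO_cZE_dE	monohydroxy-conjugated Z,E-dienes	secondary_oxidation	8	very low concentration intermediate; visible days 8-12 only
HO_EPO_mE_1	hydroxy-epoxy-monoenes (double bond between OH and epoxide)	secondary_oxidation	13	9-OH-12,13-E-epoxy-10E / 13-OH-9,10-E(Z)-epoxy-11E group; olefinic channel near 5.94-5.95
HO_EPO_mE_2	hydroxy-epoxy-monoenes (vicinal OH and epoxide, threo)	secondary_oxidation	13	threo 11-OH-12,13-E-epoxy-9E / 11-OH-9,10-E-epoxy-12E; methine carbinol q channel
HO_KO_mE	hydroxy-keto-monoenes	secondary_oxidation	14	vicinal and non-vicinal OH/keto structures, quantified jointly; 1-2 mmol/mol TG at most
mKO_cZE_dE	monoketo-conjugated Z,E-dienes	secondary_oxidation	12	maximum day 13; signal partially adjacent to furanone channel
mKO_cEE_dE	monoketo-conjugated E,E-dienes	secondary_oxidation	11	maximum day 15; more abundant than Z,E isomers
KO_EPO_mE_EE	keto-epoxy-monoenes (E-epoxide, conjugated keto-ene)	secondary_oxidation	14	13-KO-9,10-E-epoxy-11E / 9-KO-12,13-E-epoxy-10E; main late keto-epoxide
KO_EPO_mE_ZE	keto-epoxy-monoenes (Z-epoxide, conjugated keto-ene)	secondary_oxidation	14	13-KO-9,10-Z-epoxy-11E / 9-KO-12,13-Z-epoxy-10E
KO_EPO_mE_vic	keto-epoxy-monoenes (vicinal keto and epoxide)	secondary_oxidation	14	11-KO-12,13-E-epoxy-9E / 11-KO-9,10-E-epoxy-12E; very low concentration
EPO_KO_HO	epoxy-keto-hydroxy derivatives	secondary_oxidation	12	12,13-E-epoxy-11-keto-9-hydroxy-octadecanoate type; very low concentration
Z_EPO_Z_mE	Z-epoxy-Z-monoenes	secondary_oxidation	13	leukotoxin/isoleukotoxin-type epoxides from intact linoleic chains; maximum at day 16
E_EPO_Z_mE	E-epoxy-Z-monoenes	secondary_oxidation	13	E-epoxide isomers requiring prior isomerisation; maximum at day 16
dEPO	diepoxides	secondary_oxidation	NA	never detected in this system; catalogued as an absence/LOD channel only
dHO_pHO	dihydroxy and polyhydroxy structures	secondary_oxidation	12	leukotoxin/isoleukotoxin-diol-type methine carbinols; co-resonant hydroxy-epoxide signal subtracted
carbinol_398	secondary-alcohol methine carbinols (3.98 ppm group)	secondary_oxidation	12	methine carbinol protons of secondary alcohols, vicinal or not; grows to end of process
poly_ethers	poly-ether backbone structures	secondary_oxidation	13	ether-bridge methine protons from oxirane ring opening by alcohols; polymerisation marker
poly_formates	poly-formate groups	secondary_oxidation	13	formate H from oxirane ring opening by formic acid; polymerisation marker
formic_acid	formic acid	small_molecule	12	singlet; product of recurrent aldehyde oxidation
alkyl_furans	alkyl-furans	small_molecule	14	2-pentylfuran and homologues; end products
furanone_5p	5-pentyl-(5H)-furan-2-one	small_molecule	13	unsaturated lactone; end product; channel adjacent to mKO-c(Z,E)-dE signal
ald_2E_alkenals	2E-alkenals	small_molecule	11	first aldehydes together with 4-hydroperoxy-2E-alkenals
ald_4HPO_2E_alkenals	4-hydroperoxy-2E-alkenals	small_molecule	11	maximum near day 15, slight decrease at the end
ald_nalkanals	n-alkanals	small_molecule	12	saturated aldehydes
ald_24EE_alkadienals	2E,4E-alkadienals	small_molecule	12	conjugated dienals
ald_4HO_2E_alkenals	4-hydroxy-2E-alkenals	small_molecule	13	main aldehyde class at the end of the process
ald_4oxo_2E_alkenals	4-oxo-2E-alkenals	small_molecule	13	oxygenated alpha,beta-unsaturated aldehydes
ald_45EPO_2E_alkenals	4,5-epoxy-2E-alkenals	small_molecule	13	oxygenated alpha,beta-unsaturated aldehydes
ald_23EPO_alkanals	2,3-epoxyalkanals	small_molecule	15	last aldehyde class to appear
epoxysterol_5a6a	5alpha,6alpha-epoxysterols (sitosterol+campesterol)	sterol_oxide	14	very low concentration sterol oxidation products
epoxysterol_5b6b	5beta,6beta-epoxysterols (sitosterol+campesterol)	sterol_oxide	14	very low concentration sterol oxidation products
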