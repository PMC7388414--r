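# Validated mature toxins of the Acanthoscurria rondoniae venom peptidome.
# reported_mass is the published monoisotopic mass (Da); mass_sequence +
# modifications give the molecular form whose theoretical mass matches it
# (U2-TRTX-Ar1a: des-Gly C-terminal amidation; U1-TRTX-Ar1b: N-terminal
# acetylation). VLPPLKF is flagged mass_discrepant (~140 ppm off theory).
toxin_id	reported_mass	sequence	aa	ss_bonds	log_intensity	rank	family	is_crp	modifications	mass_sequence	mass_discrepant
PLPVFV	670.41	PLPVFV	6	0	6.38	15	short	FALSE		PLPVFV	FALSE
VVVPFVV	757.47	VVVPFVV	7	0	8.54	9	short	FALSE		VVVPFVV	FALSE
VENLAEP	770.39	VENLAEP	7	0	8.78	8	short	FALSE		VENLAEP	FALSE
VLPPLKF	812.4	VLPPLKF	7	0	7.6	13	short	FALSE		VLPPLKF	TRUE
VPPILKY	828.51	VPPILKY	7	0	5.91	18	short	FALSE		VPPILKY	FALSE
YPPPPPPPH	997.5	YPPPPPPPH	9	0	6.21	16	short	FALSE		YPPPPPPPH	FALSE
FETPNNPDGKVTKQE	1702.82	FETPNNPDGKVTKQE	15	0	6.08	17	short	FALSE		FETPNNPDGKVTKQE	FALSE
U1-TRTX-Agm3a	3690.49	ACGSFMWKCSERLPCCQEYVCSPQWKWCQNP	31	3	9.49	2	U1-Agm	TRUE		ACGSFMWKCSERLPCCQEYVCSPQWKWCQNP	FALSE
U1-TRTX-Ar1a	3852.54	SCVHERETCSKVRGPLCCRGECTCPIYGDCFCYGS	35	4	9.08	4	U1	TRUE		SCVHERETCSKVRGPLCCRGECTCPIYGDCFCYGS	FALSE
U1-TRTX-Ar1b	3920.58	SCVYERETCSKVRGPLCCRGECTCPIYGDCFCYGS	35	4	8.05	12	U1	TRUE	acetylation	SCVYERETCSKVRGPLCCRGECTCPIYGDCFCYGS	FALSE
U2-TRTX-Ar1a	4876.02	CATENVPCDENRPGDCCSEYECLKPTGHGWWYASYYCYKKKSG	43	3	8.91	6	U2	TRUE	amidation	CATENVPCDENRPGDCCSEYECLKPTGHGWWYASYYCYKKKS	FALSE
U3-TRTX-Ar1a	5439.8	IIECFFSCEIEKDGKSKEGKPCKPKGDKDKDKKCSGGWRCKLKLCLKI	48	3	10.29	10	U3	TRUE		IIECFFSCEIEKDGKSKEGKPCKPKGDKDKDKKCSGGWRCKLKLCLKI	FALSE
U3-TRTX-Ar1b	5457.75	IIECFFSCEIEKDGKSKEGKPCKPKGDKDKDKKCSGGWRCKLKMCLKI	48	3	10.54	1	U3	TRUE		IIECFFSCEIEKDGKSKEGKPCKPKGDKDKDKKCSGGWRCKLKMCLKI	FALSE
U4-TRTX-Ar1a	6728.19	ECKQLKEKCSNHCDCCGKTVLCATVYVGRNTEMLCKEKRSDDPILNSIGKVINAATKAMSGC	62	4	9.36	3	U4	TRUE		ECKQLKEKCSNHCDCCGKTVLCATVYVGRNTEMLCKEKRSDDPILNSIGKVINAATKAMSGC	FALSE
U4-TRTX-Ar1b	6755.19	ECKQLKEKCNNHCDCCGKTVLCATVYVGRNTEMLCKEKRSDDPILNSIGKVINAATKAMSGC	62	4	8.8	7	U4	TRUE		ECKQLKEKCNNHCDCCGKTVLCATVYVGRNTEMLCKEKRSDDPILNSIGKVINAATKAMSGC	FALSE
U5-TRTX-Ar1a	6928.76	ACTTEADCPNGCCTGGSFHRYCRSYGGEMDQCEPRNDFGSYSTACPCKEEFECSPIKRCQRR	62	5	8.32	11	U5	TRUE		ACTTEADCPNGCCTGGSFHRYCRSYGGEMDQCEPRNDFGSYSTACPCKEEFECSPIKRCQRR	FALSE
U6-TRTX-Ar1a	6936.18	NREHCYIPRRRCVTTEQCCKPYDTVNYFVACGKAWPEDKKRKVNKCYICNNELTVCTR	58	4	7.56	14	U6	TRUE		NREHCYIPRRRCVTTEQCCKPYDTVNYFVACGKAWPEDKKRKVNKCYICNNELTVCTR	FALSE
U7-TRTX-Ar1a	7195.23	ETSCIEELQTCKNSCECCGTTTICSPSWVDGNEIKLCRNEGNKLQKVWHFFQKAYSKMHSCKT	63	4	8.98	5	U7	TRUE		ETSCIEELQTCKNSCECCGTTTICSPSWVDGNEIKLCRNEGNKLQKVWHFFQKAYSKMHSCKT	FALSE
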