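# Antimicrobial (iAMPpred-style) and anticancer (random-forest / SVM)
# predictor scores for the 18 validated toxins and 6 positive-control
# peptides. Scores are external predictor outputs consumed as inputs.
peptide_id	role	is_crp	family	antibacterial	antiviral	antifungal	rf_acp	svm_acp
Gomesin	control			0.985	0.898	0.973	0.668	0.926
Rondonin	control			0.671	0.301	0.903	0.4	0.447
P9	control			0.997	0.94	0.992	0.479	0.816
mBD4	control			0.99	0.773	0.968	0.371	0.837
Aurein 1.2	control			0.94	0.913	0.917	0.87	0.935
HNP-1	control			0.92	0.92	0.95	0.879	0.938
PLPVFV	toxin	FALSE	short	0.623	0.586	0.515	0.639	0.656
VVVPFVV	toxin	FALSE	short	0.645	0.538	0.432	0.637	0.635
VENLAEP	toxin	FALSE	short	0.083	0.046	0.028	0.296	0.508
VLPPLKF	toxin	FALSE	short	0.801	0.794	0.828	0.632	0.74
VPPILKY	toxin	FALSE	short	0.751	0.41	0.429	0.501	0.528
YPPPPPPPH	toxin	FALSE	short	0.542	0.382	0.406	0.442	0.618
FETPNNPDGKVTKQE	toxin	FALSE	short	0.133	0.143	0.082	0.35	0.164
U1-TRTX-Agm3a	toxin	TRUE	U1-Agm	0.843	0.696	0.579	0.559	0.878
U1-TRTX-Ar1a	toxin	TRUE	U1	0.994	0.968	0.976	0.489	0.862
U1-TRTX-Ar1b	toxin	TRUE	U1	0.987	0.966	0.972	0.541	0.903
U2-TRTX-Ar1a	toxin	TRUE	U2	0.94	0.685	0.92	0.283	0.624
U3-TRTX-Ar1a	toxin	TRUE	U3	0.996	0.918	0.982	0.292	0.36
U3-TRTX-Ar1b	toxin	TRUE	U3	0.997	0.924	0.986	0.324	0.381
U4-TRTX-Ar1a	toxin	TRUE	U4	0.981	0.77	0.954	0.139	0.121
U4-TRTX-Ar1b	toxin	TRUE	U4	0.978	0.742	0.937	0.142	0.128
U5-TRTX-Ar1a	toxin	TRUE	U5	0.996	0.858	0.989	0.363	0.519
U6-TRTX-Ar1a	toxin	TRUE	U6	0.986	0.826	0.947	0.3	0.538
U7-TRTX-Ar1a	toxin	TRUE	U7	0.991	0.855	0.926	0.256	0.302
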