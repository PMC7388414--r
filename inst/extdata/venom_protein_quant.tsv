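# Hi3 quantification of the 33 Acanthoscurria rondoniae venom proteins
# retained by the identification filters (>= 3 peptides, >= 2 of 3
# replicates). ni = normalised Hi3 intensity; reported_percent as
# published (1 decimal).
accession	peptide_count	mass_kda	description	ni	reported_percent
comp117964_c0_seq1.p1	181	53.3	Ar-CRISP	13800000	27.9
comp90511_c0_seq1.p1	28	10.7	U3-TRTX-Ar1a	12900000	25.9
comp105543_c0_seq1.p3	25	9.4	U5-TRTX-Ar1a	7290000	14.7
comp127239_c0_seq1.p1	101	82.4	Ar-Neprilysin-1	4160000	8.4
comp57753_c0_seq1.p1	13	12.3	U4-TRTX-Ar1a	4130000	8.3
comp90508_c2_seq2.p1	5	15	U2-TRTX-Ar1a	2510000	5.1
comp107050_c0_seq2.p2	12	13	U7-TRTX-Ar1a	1470000	3
comp127127_c4_seq1.p1	46	49.8	Ar-Hyaluronidase	749000	1.5
comp125618_c0_seq2.p1	5	6.9	U1-TRTX-Agm3a	681000	1.4
comp90482_c0_seq1.p1	26	48.6	PFAM: Serpin (serine protease inhibitor)	425000	0.9
comp98439_c0_seq1.p1	4	16.3	PFAM: Thyroglobulin type-1 repeat	323000	0.7
comp117041_c0_seq1.p1	28	42.8	PFAM: Tyrosine phosphatase family	245000	0.5
comp57865_c0_seq1.p1	7	18.5	Unknown	186000	0.4
comp99029_c0_seq1.p1	4	10.8	U6-TRTX-Ar1a	162000	0.3
comp117273_c1_seq1.p1	23	45.1	PFAM: Putative serine esterase (DUF676)	146000	0.3
comp119317_c0_seq2.p1	20	87.2	PFAM: Peptidase family M13	128000	0.3
comp116850_c0_seq2.p1	9	53.1	PFAM: Zinc carboxypeptidase	69300	0.1
comp122884_c0_seq2.p1	5	78.9	PFAM: Peptidase S8 pro-domain	49900	0.1
comp117075_c0_seq1.p1	3	25.5	PFAM: Tetraspanin family	46100	0.1
comp115582_c0_seq1.p1	10	76.4	PFAM: Neutral/alkaline nonlysosomal ceramidase	43000	0.1
comp113427_c0_seq1.p1	11	91.1	PFAM: Fasciclin domain	41500	0.1
comp87917_c0_seq1.p1	5	12.2	TSA: U3-hexatoxin-Hib [Hadronyche infensa]	19800	0
comp27569_c0_seq1.p1	3	27.4	TSA: putative uncharacterized protein. partial	15300	0
comp126642_c0_seq1.p1	3	46.1	PFAM: Cysteine-rich secretory protein family	11600	0
comp114378_c0_seq1.p1	18	72.2	PFAM: Hemocyanin. copper containing domain	7960	0
comp120272_c1_seq8.p1	3	39.9	TSA: peptidylglycine alpha-hydroxylating monooxygenase	4760	0
comp121853_c0_seq2.p1	6	72.3	PFAM: Angiotensin-converting enzyme	4540	0
comp114378_c0_seq4.p1	17	71.5	PFAM: Hemocyanin. copper containing domain	2720	0
comp117984_c0_seq2.p1	4	31.1	PFAM: Immunoglobulin I-set domain	2600	0
comp57921_c1_seq1.p1	4	44.9	PFAM: Hemocyanin. ig-like domain	799	0
comp114578_c0_seq3.p1	7	25.1	TSA: tri-cap-1 [Trittame loki]	491	0
comp114378_c0_seq2.p1	16	73.7	PFAM: Hemocyanin. ig-like domain	171	0
comp86283_c0_seq1.p1	6	78.4	PFAM: Transferrin	0	0
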