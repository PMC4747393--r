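subject_id	family_id	age_ec	ec_histology	ec_grade	ec_stage	msi	other_tumors	phenotype_override	mmr_gene	mmr_cdna	mmr_protein	ngs_ok
11	D	38	endometrioid	1	1a	I			MSH2	c.244A>T	p.Lys82*	TRUE
12	D	46	endometrioid	3	1b	S			MSH2	c.244A>T	p.Lys82*	TRUE
16	D	38	na	na	na	na	C-29;C-43		MSH2	c.244A>T	p.Lys82*	TRUE
17	E	46	endometrioid	na	na	S			MSH2	c.212-2A>G	splice	TRUE
19	E	53	na	na	na	na			MSH2	c.212-2A>G	splice	TRUE
26	F	49	endometrioid	1	1a	na			MSH6	c.1139_1143delATGAG	p.Asp380Alafs*6	TRUE
28	F	55	endometrioid	1	1b	na			MSH6	c.1139_1143delATGAG	p.Asp380Alafs*6	TRUE
18	G	44	endometrioid	1	na	I			MLH1	c.2149_2195dup	p.His733Asnfs*66	TRUE
29	G	39	na	na	na	na	O-na		MLH1	c.2149_2195dup	p.His733Asnfs*66	TRUE
2	A	52	endometrioid	2	1b	S			MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
3	A	65	serous	3	1c	I	C-59		MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
6	B	51	endometrioid	1	1b	S			MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
7	B	62	endometrioid	3	2	I	C-70;U-81		MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
8	C	54	endometrioid	1	1a	I			MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
9	C	52	endometrioid	1	1	S	B-na		MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
1		50	endometrioid	1	2	I			MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
4		57	endometrioid	3	na	I			MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
5		62	endometrioid	1	1b	I			MSH6	c.3729_3732dupATTA	p.Phe1245Ilefs*31	TRUE
10		40	endometrioid	1	na	na	O-40		MSH6	c.1444C>T	p.Arg482*	TRUE
13		81	na	na	na	na	C-59		PMS2	c.989-296_1144+706del	p.Glu330_Glu381del	TRUE
14		31	na	na	na	na			MSH6	c.3772C>T	p.Gln1258*	TRUE
15		49	endometrioid	1	3	S	O-49		MSH6	c.2569_2572del	p.Asp857Phefs*10	TRUE
20		56	endometrioid	na	na	S	B-50		MSH6	c.2191C>T	p.Gln731*	TRUE
21		58	endometrioid	1	1b	I	C-58		MLH1	c.901C>T	p.Gln301*	TRUE
22		60	endometrioid	1	3	na			MSH6	c.2815C>T	p.Gln939*	FALSE
23		49	endometrioid	1	1b	I			PMS2	c.24-12_107del96	p.Ser8Argfs*5	TRUE
24		61	endometrioid	3	1b	I	C-56		MSH6	c.4002-22_4002-4del19	splice	TRUE
25		44	endometrioid	1	na	I			MSH6	c.3838C>T	p.Gln1280*	FALSE
27		40	na	na	na	S			MSH2	c.212-?_366+?del	p.Ala72Phefs*9	TRUE
30		71	endometrioid	2	3	I			MSH2	c.646-2A>G	splice	TRUE
31		50	mixed	3	1b	I			MSH6	c.2191C>T	p.Gln731*	TRUE
32		64	endometrioid	1	1a	S			MSH6	c.2926_2929dupCGTT	p.Tyr977Serfs*8	TRUE
33		49	endometrioid	1	1b	I			MSH6	c.1804_1805del	p.Ser602Lysfs*4	TRUE
34		75	endometrioid	1	1b	na	C-na		MSH6	c.3794_3801del	p.His1266Metfs*6	TRUE
35		64	endometrioid	1	1b	I			MSH6	c.3949_3965del	p.His1317Ilefs*2	TRUE
37		53	na	na	na	na	C-52		MSH2	c.1203dup	p.Gln402Thrfs*15	TRUE
38		55	endometrioid	2	1	I			MSH6	c.3185G>T	p.Cys1062Phe	TRUE
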