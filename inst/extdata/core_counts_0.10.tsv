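otu	A1	A2	O1	O2	O3	evenness	total	taxonomy
Otu1237	4	8	9	9	8	0.979	38	WCHB1-60;
Otu1558	15	6	8	7	6	0.956	42	Proteobacteria;Gammaproteobacteria;Legionellales;Coxiellaceae;Aquicella;
Otu1464	9	21	3	16	12	0.912	61	Proteobacteria;Deltaproteobacteria;Myxococcales;Nannocystineae;Haliangiaceae;Haliangium;
Otu1410	11	10	9	7	4	0.969	41	Proteobacteria;Deltaproteobacteria;GR-WP33-30;uncultured;
Otu1537	21	3	13	20	14	0.921	71	Proteobacteria;Betaproteobacteria;TRA3-20;
Otu1534	11	22	7	10	15	0.953	65	Proteobacteria;Betaproteobacteria;SC-I-84;
Otu1572	41	21	23	25	53	0.957	163	Proteobacteria;Betaproteobacteria;Nitrosomonadales;Nitrosomonadaceae;uncultured;
Otu1489	11	19	18	4	6	0.909	58	Proteobacteria;Betaproteobacteria;Burkholderiales;Comamonadaceae;
Otu1428	37	46	36	74	48	0.977	241	Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae;
Otu1248	10	5	3	5	13	0.919	36	Proteobacteria;Alphaproteobacteria;Rickettsiales;Holosporaceae;Holospora;
Otu1434	35	38	45	36	8	0.938	162	Proteobacteria;Alphaproteobacteria;Rhodospirillales;
Otu1574	7	18	13	26	13	0.948	77	Proteobacteria;Alphaproteobacteria;Rhodospirillales;
Otu1524	12	23	19	19	3	0.916	76	Proteobacteria;Alphaproteobacteria;Rhizobiales;Methylocystaceae;uncultured;
Otu1557	10	13	18	17	3	0.926	61	Proteobacteria;Alphaproteobacteria;Caulobacterales;Caulobacteraceae;
Otu1531	7	4	4	4	3	0.973	22	Chloroflexi;TK10;
Otu1522	28	19	11	14	6	0.928	78	Chloroflexi;S085;
Otu1594	101	56	45	59	55	0.973	316	Chloroflexi;KD4-96;
Otu1504	20	20	10	20	25	0.977	95	Candidate_division_TM7;
Otu1589	74	11	96	61	58	0.915	300	Bacteroidetes;Sphingobacteria;Sphingobacteriales;Cytophagaceae;Flexibacter;
Otu1573	23	79	79	140	40	0.902	361	Bacteroidetes;Sphingobacteria;Sphingobacteriales;Chitinophagaceae;
Otu1470	42	109	90	72	54	0.966	367	Acidobacteria;Acidobacteria;Acidobacteriales;Acidobacteriaceae;Candidatus_Solibacter;
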