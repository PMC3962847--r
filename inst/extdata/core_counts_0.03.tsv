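otu	A1	A2	O1	O2	O3	evenness	total	taxonomy
Otu4707	4	3	4	6	6	0.979	23	Proteobacteria;Alphaproteobacteria;Rickettsiales;Holosporaceae;Holospora;
Otu5214	13	26	24	36	41	0.960	140	Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae;Sphingomonas;
Otu3722	11	3	12	4	9	0.925	39	Chloroflexi;KD4-96;
Otu4868	6	17	18	15	3	0.903	59	Acidobacteria;Acidobacteria;Acidobacteriales;Acidobacteriaceae;
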