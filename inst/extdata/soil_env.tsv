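sample	OM	C_ino	P2O5	H2O	pH	Fe2O3	Cd_t	Cd_ba	Pb_t	Pb_ba	Zn_t	Zn_ba	Cr_t	Cr_ba
A1	2.82	0.12	0.02	2.18	7.0	2.23	4.2	2.5	204	104	749	521	740	492
A2	4.62	0.09	0.09	2.77	6.5	3.23	3.5	2.1	203	99	767	538	760	501
O1	19.90	0.30	0.13	5.60	6.7	2.02	3.4	2.1	1378	730	1247	863	100	63
O2	16.23	0.62	0.05	2.95	6.5	1.06	3.9	2.3	461	241	957	692	180	121
O3	3.82	30.37	0.01	1.07	7.6	7.43	3.7	2.2	1097	563	2002	1478	300	196
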