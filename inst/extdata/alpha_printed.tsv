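sample	sobs_003	sobs_010	chao1_003	chao1_010	ace_003	ace_010	shannon_003	shannon_010	pd
A1	858	386	3025	981	5188	1554	6.367	4.984	53.34
A2	826	342	2530	881	4515	1347	6.309	4.800	49.14
O1	699	263	1589	436	2596	576	5.978	4.280	40.32
O2	749	312	1728	523	2723	637	6.196	4.810	45.63
O3	476	224	1069	402	1768	571	5.321	4.169	30.66
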