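CHROM	POS	GENE	FREQ	BETA_DBP	BETA_SBP	VE_DBP_PCT	VE_SBP_PCT
3	47956424	MAP4	0.34354	-3.93	-6.09	7.88	7.01
1	175092674	TNN	0.64771	3.38	4.10	5.89	3.20
1	66075952	LEPR	0.15466	3.49	3.78	3.61	1.56
3	48040283	MAP4	0.02805	-5.03	-7.80	1.56	1.39
3	47957996	MAP4	0.02290	-4.41	-6.84	0.98	0.87
1	151501841	CGN	0.10396	-2.63	0	1.46	0
13	28624294	FLT3	0.61400	1.40	1.44	1.05	0.41
3	48040284	MAP4	0.00695	-5.05	-7.83	0.40	0.36
1	175092637	TNN	0.02007	3.38	4.10	0.51	0.28
1	151491026	CGN	0.02084	-2.88	0	0.38	0
1	175046835	TNN	0.01390	2.88	3.49	0.26	0.14
3	47908815	MAP4	0.00257	-4.99	-7.73	0.15	0.13
11	77937768	GAB2	0.00386	0	6.04	0	0.12
1	175046652	TNN	0.00824	3.35	4.06	0.20	0.11
9	123605126	PSMD5	0.18837	-0.58	-0.89	0.11	0.10
3	58109162	FLNB	0.45677	0.13	0.64	0.01	0.08
1	151503071	CGN	0.01132	-2.88	0	0.21	0
1	175054626	TNN	0.00566	3.30	4.00	0.14	0.08
1	53712727	LRP8	0.21410	0	-0.71	0	0.07
19	46812451	HIF3A	0.03886	1.36	0.92	0.16	0.03
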