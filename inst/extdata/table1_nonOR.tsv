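gene_id	family	fpkm_f_ant	fpkm_m_ant
EposABPX1	ABPX	194673	305620
EposCYP21	CYP	34	26
EposIR1	IR	21	15
EposABPX2	ABPX	27310	27431
EposCYP22	CYP	113	66
EposIR3	IR	101	66
EposABPX3	ABPX	75729	126520
EposCYP23	CYP	372	111
EposIR4	IR	72	24
EposABPX4	ABPX	21668	19058
EposCYP24	CYP	240	68
EposIR7d	IR	14	7
EposABPX5	ABPX	664	327
EposCYP25	CYP	4	4
EposIR8a	IR	766	504
EposABPX6	ABPX	24780	18822
EposCYP26	CYP	60	19
EposIR21a	IR	53	27
EposCSP1	CSP	30415	26582
EposCYP27	CYP	44	24
EposIR25a	IR	185	123
EposCSP2	CSP	51286	17848
EposCYP28	CYP	42	7
EposIR41a	IR	60	35
EposCSP3	CSP	17920	12770
EposCYP29	CYP	14	11
EposIR68	IR	51	31
EposCSP4	CSP	98800	80082
EposCYP30	CYP	88	39
EposIR75b	IR	31	16
EposCSP5	CSP	52504	6969
EposCYP31	CYP	66	39
EposIR75d	IR	10	9
EposCSP6	CSP	87	123
EposCYP32	CYP	19	9
EposIR75e	IR	44	27
EposCSP7	CSP	88271	41531
EposCYP33	CYP	21	12
EposIR75p	IR	31	11
EposCSP8	CSP	122	27
EposCYP34	CYP	8	13
EposIR75q.1	IR	20	11
EposCSP9	CSP	496	90
EposCYP35	CYP	4	2
EposIR75q.2	IR	295	225
EposCSP10	CSP	102	16
EposCYP36	CYP	493	322
EposIR76b	IR	341	277
EposCSP11	CSP	105	69
EposCYP37	CYP	13	13
EposIR87a	IR	127	77
EposCSP12	CSP	79	26
EposCYP38	CYP	23	140
EposIR93a	IR	4	1
EposCSP13	CSP	64	12
EposCYP39	CYP	92	38
EposOBP1	OBP	1790	673
EposCXE1	CXE	7	6
EposCYP40	CYP	6	8
EposOBP2	OBP	23	13
EposCXE6	CXE	6	3
EposCYP41	CYP	38	10
EposOBP2b	OBP	35	14
EposCXE7	CXE	13	9
EposCYP42	CYP	81	30
EposOBP2c	OBP	165	78
EposCXE14	CXE	17	17
EposCYP43	CYP	111	72
EposOBP3	OBP	5652	1098
EposCXE15	CXE	59	77
EposCYP44	CYP	177	87
EposOBP4	OBP	632	337
EposCXE16	CXE	105	95
EposCYP45	CYP	61	34
EposOBP5	OBP	2909	716
EposCXE17	CXE	207	101
EposCYP46	CYP	54	142
EposOBP6	OBP	203263	67477
EposCXE18	CXE	39	32
EposCYP47	CYP	47	12
EposOBP7	OBP	159629	45042
EposCXE21	CXE	18	7
EposCYP48	CYP	119	710
EposOBP8	OBP	51	19
EposCXE22	CXE	76	47
EposCYP49	CYP	491	164
EposOBP9	OBP	274	114
EposCXE23	CXE	21	8
EposCYP50	CYP	15	3
EposOBP10	OBP	147	45
EposCXE24	CXE	10	5
EposCYP51	CYP	40	25
EposOBP11	OBP	365	11
EposCXE25	CXE	110	83
EposGOBP1	GOBP	18273	10673
EposOBP12	OBP	95	32
EposCXE26	CXE	65	80
EposGOBP2	GOBP	241065	175652
EposOBP13	OBP	1302	15
EposCXE27	CXE	15	9
EposGR1	GR	8	1
EposOBP13b	OBP	6895	36
EposCXE28	CXE	68	23
EposGR2	GR	7	5
EposOBP14	OBP	173	700
EposCXE29	CXE	19	12
EposGR3	GR	3	3
EposOBP15	OBP	2048	1051
EposCXE30	CXE	22	9
EposGR4	GR	18	8
EposOBP16	OBP	259	197
EposCXE31	CXE	12	8
EposGR5	GR	18	14
EposOBP17	OBP	10	19
EposCXE32	CXE	3	1
EposGR6	GR	51	25
EposOBP18	OBP	317386	78324
EposCXE33	CXE	24	14
EposGR7	GR	64	23
EposOBP19	OBP	8234	6170
EposCXE34	CXE	14	12
EposGR8	GR	59	32
EposOBP20	OBP	2113	1243
EposCXE35	CXE	42	21
EposGR9	GR	42	4
EposPBP1	PBP	97046	863482
EposCXE36	CXE	5	6
EposGST2	GST	332	203
EposPBP2	PBP	48920	10709
EposCXE37	CXE	98	53
EposGST4	GST	6241	6532
EposPBP3	PBP	14081	50553
EposCXE38	CXE	65	39
EposGST5	GST	518	372
EposSNMP1	SNMP	855	364
EposCXE39	CXE	22	15
EposGST6	GST	130	81
EposSNMP2	SNMP	501	344
EposCYP1	CYP	132	87
EposGST7	GST	1000	1800
EposTO1	TO	103597	50124
EposCYP3	CYP	61	20
EposGST8	GST	1267	472
EposTO2	TO	950	834
EposCYP4	CYP	162	114
EposGST9	GST	5264	3256
EposTO3	TO	3735	2115
EposCYP5	CYP	113	65
EposGST10	GST	346	202
EposTO4	TO	3774	3826
EposCYP6	CYP	1532	956
EposGST11	GST	17621	17056
EposTO5	TO	59	49
EposCYP7	CYP	118	42
EposGST12	GST	245	134
EposTO6	TO	48	13
EposCYP9	CYP	535	164
EposGST13	GST	708	259
EposTO7	TO	60	13
EposCYP10	CYP	360	107
EposGST14	GST	337	412
EposTO8	TO	322	38
EposCYP11	CYP	13	15
EposGST15	GST	48	48
EposTO9	TO	342	228
EposCYP12	CYP	223	116
EposGST16	GST	190	94
EposTO10	TO	402	444
EposCYP13	CYP	4	6
EposGST17	GST	755	552
EposTO11	TO	33	7
EposCYP14	CYP	9519	5579
EposGST18	GST	149	85
EposTO12	TO	200	83
EposCYP15	CYP	73	39
EposGST19	GST	123	77
EposTO13	TO	263	33
EposCYP16	CYP	60	10
EposGST20	GST	406	197
EposTO14	TO	2668	2416
EposCYP17	CYP	44	22
EposGST21	GST	59	11
EposTO15	TO	74	18
EposCYP18	CYP	6592	3419
EposGST22	GST	69	68
EposTO16	TO	14	6
EposCYP19	CYP	82	17
EposIgluR	IgluR-like	14	6
EposTO17	TO	8	3
EposCYP20	CYP	1315	732
EposTO18	TO	11	7
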