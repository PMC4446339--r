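gene_id	qpcr_f_ant	qpcr_f_body	qpcr_m_ant	qpcr_m_body	fpkm_f_ant	fpkm_m_ant
EposOR1	0.03263	0.00024	0.07130	BLD	191	104
EposOrco	2.62100	BLD	3.55188	BLD	2676	1397
EposOR3	0.00768	BLD	0.00663	BLD	35	30
EposOR4	0.03408	BLD	0.03337	0.00011	72	53
EposOR5	0.01009	0.00002	0.00138	BLD	319	37
EposOR6	0.00073	BLD	0.04183	0.00600	0	12
EposOR7	0.00315	0.00010	0.01561	0.00138	0	90
EposOR8	0.00053	BLD	0.00006	0.00002	0	0
EposOR9	0.00145	BLD	0.00127	BLD	18	6
EposOR10	0.00791	0.00007	0.00624	0.00115	37	9
EposOR11	BLD	BLD	BLD	BLD	0	0
EposOR12	0.00143	BLD	0.00192	0.00001	74	74
EposOR13	0.00028	0.00004	0.00071	0.00059	0	0
EposOR14	0.01350	0.00003	0.00650	0.00028	35	12
EposOR15	0.03509	0.00502	0.02606	0.02465	73	34
EposOR16	0.00265	BLD	0.00726	0.00023	3	1
EposOR17	0.00560	0.00493	0.01428	0.00325	2	1
EposOR18	0.03153	0.00029	0.02091	BLD	63	28
EposOR19	0.07996	0.00007	0.03561	BLD	288	57
EposOR20	0.01524	0.00139	0.01714	0.00381	74	23
EposOR21	0.00729	0.00002	0.00099	0.00003	66	6
EposOR22	0.07837	0.00007	0.02709	BLD	108	43
EposOR23	0.00058	0.00025	0.00145	0.00108	1	1
EposOR24	0.01978	BLD	0.02527	BLD	20	9
EposOR25	0.03330	0.00034	0.03440	0.00260	46	15
EposOR26	0.05425	0.01337	0.11274	0.01719	21	15
EposOR27	0.05022	BLD	0.04528	0.00128	104	46
EposOR28	0.01670	BLD	0.00903	0.00009	22	20
EposOR29	0.04849	0.00020	0.02772	0.00027	36	18
EposOR30	0.02020	0.00398	0.69629	0.02740	0	536
EposOR31	0.00616	BLD	0.00003	BLD	189	0
EposOR32	0.04552	BLD	0.03881	BLD	18	6
EposOR33	0.00640	BLD	0.00047	0.00004	60	0
EposOR34	0.01131	0.00043	0.32708	0.00233	1	779
EposOR35	0.00408	BLD	0.00543	BLD	26	14
EposOR36	0.02528	BLD	0.00014	0.00004	57	0
EposOR37	0.00393	0.00008	0.01092	0.00008	20	17
EposOR38	0.04631	0.00006	0.11024	0.00197	50	19
EposOR39	0.09887	BLD	0.19689	BLD	50	24
EposOR40	0.32466	0.00007	0.00507	0.00135	383	1
EposOR41	0.00446	0.00019	0.00911	BLD	29	19
EposOR42	0.05713	BLD	0.09239	BLD	70	47
EposOR43	0.09436	0.00068	0.04906	0.00181	21	17
EposOR44	0.00199	BLD	0.00317	BLD	44	19
EposOR45	0.01907	0.00015	0.02347	0.00011	147	75
EposOR46	0.00932	0.00015	0.01168	0.00079	28	16
EposOR47	0.08845	0.00096	0.07746	0.00430	52	31
EposOR48	0.06465	0.00007	0.07733	0.00034	102	75
EposOR49	0.00271	0.00022	0.00522	0.00008	6	5
EposOR50	0.00054	0.00008	0.00144	0.00010	3	1
EposOR51	0.05788	0.00038	0.06611	0.00031	163	84
EposOR52	0.00986	BLD	0.00955	BLD	24	9
EposOR53	0.01144	0.00003	0.01077	0.00011	128	92
EposOR54	0.02487	0.00003	0.02158	0.00011	47	23
EposOR55	0.00098	0.00001	0.00569	0.00026	37	28
EposOR56	0.00100	BLD	0.00071	BLD	10	4
EposOR57	0.00114	BLD	0.00610	0.00001	8	3
EposOR58	0.00405	0.00001	0.00339	0.00003	81	40
EposOR59	0.01240	0.00061	0.00962	0.00044	11	3
EposOR60	0.00464	0.00010	0.01035	BLD	38	32
EposOR61	0.01409	0.00006	0.01719	BLD	160	50
EposOR62	0.00589	BLD	0.00451	BLD	30	16
EposOR63	0.00017	BLD	0.00011	BLD	7	3
EposOR64	0.05393	BLD	0.01088	BLD	227	56
EposOR65	0.01115	0.00005	0.00184	0.00004	108	17
EposOR66	0.00506	0.00020	0.00296	BLD	14	4
EposOR67	0.02124	0.00001	0.01068	0.00007	128	43
EposOR68	0.02752	0.00027	0.02945	BLD	55	32
EposOR69	BLD	BLD	BLD	BLD	0	0
EposOR70	BLD	BLD	BLD	BLD	1	0
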