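chrom_pair	segment	global_gc_h	global_gc_l	predicted_h	predicted_l	hom_h	hom_l	nonhom_h	nonhom_l
Chr1	all	45.27	45.31	692	649	617	617	75	32
Chr2	all	45.34	45.58	585	519	463	463	122	56
Chr3	all	45.93	45.77	595	562	531	531	64	31
Chr4	all	45.24	45.30	561	547	499	499	62	48
Chr5	all	44.85	45.04	497	454	421	421	76	33
Chr6	all	45.82	45.81	452	422	408	408	44	14
Chr7	all	45.82	45.68	384	345	322	322	62	23
Chr8	all	45.59	45.65	387	382	354	354	33	28
Chr9	all	45.75	45.36	364	340	299	299	65	41
Chr10	all	45.21	44.83	358	364	291	291	67	73
Chr10	A	NA	NA	308	285	256	256	52	29
Chr10	B	NA	NA	79	50	35	35	44	15
Chr11	all	45.89	45.83	343	314	297	297	46	17
Chr12	all	45.75	46.12	381	343	320	320	61	23
Chr13	all	45.17	45.39	356	332	301	301	55	31
Chr14	all	45.91	45.64	360	332	293	293	67	39
Chr15	all	45.50	45.51	338	326	303	303	35	23
Chr16	all	45.81	46.14	307	271	255	255	52	16
Chr17	all	46.41	45.81	294	288	260	260	34	28
Chr18	all	45.73	45.48	291	263	242	242	49	21
Chr19	all	46.22	45.78	310	297	282	282	28	15
Chr20	all	45.95	45.73	263	234	214	214	49	20
Chr21	all	45.17	45.40	273	265	252	252	21	13
Chr22	all	46.02	45.94	247	238	218	218	29	20
Chr23	all	45.07	45.42	250	231	215	215	35	16
Chr24	all	45.81	45.82	250	212	199	199	51	13
Chr25	all	45.38	45.21	216	203	191	191	25	12
Chr26	all	45.65	44.56	165	130	118	118	47	12
Chr27	all	46.11	45.32	107	118	96	96	11	22
Chr28	all	44.58	45.34	119	101	92	92	27	9
Chr29	all	46.38	45.38	129	114	103	103	26	11
Chr30	all	45.60	45.45	121	117	102	102	19	15
Chr31	all	45.36	45.63	89	78	74	74	15	4
Chr32	all	45.88	45.71	79	73	67	67	12	6
Chr33	all	44.92	46.05	63	57	54	54	9	3
Chr34	all	46.24	46.36	54	50	47	47	7	3
Chr35	all	44.42	44.99	43	40	35	35	8	5
Chr36	all	46.20	46.16	50	47	42	42	8	5
Chr37	all	46.48	46.42	45	34	34	34	11	0
Chr38	all	46.93	45.68	34	37	33	33	1	4
Chr39	all	45.55	45.80	33	27	27	27	6	0
Chr40	all	45.58	45.42	25	21	19	19	6	2
Chr41	all	44.86	44.34	10	16	8	8	2	8
Chr42	all	46.05	43.60	9	11	9	9	0	2
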