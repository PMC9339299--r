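# tetradkit bundled data: per-interval tetrad counts from dissections of
# wild-type, htz1, hho1 and htz1 hho1 S. cerevisiae diploids, with the
# values printed alongside them in the source tabulation (map distance and
# SE in cM at 1 decimal, NPD obs/exp interference ratio and SE at 2
# decimals; NA = not determined, no NPD tetrads observed).
strain	interval	chrom	PD	TT	NPD	cM_printed	se_printed	ratio_printed	ratio_se_printed	pct_printed
wild_type	HIS4-CEN3	III	230	251	4	28.4	1.6	0.14	0.07	100
wild_type	CEN3-MAT	III	320	165	4	19.3	1.6	0.43	0.22	100
wild_type	MAT-RAD18	III	176	305	6	35.0	1.7	0.11	0.05	100
wild_type	RAD18-HMR	III	306	179	4	20.8	1.6	0.36	0.18	100
wild_type	SPO11-SPO13	VIII	166	301	17	41.6	2.5	0.33	0.09	100
wild_type	SPO13-THR1	VIII	386	89	2	10.6	1.2	0.84	0.60	100
wild_type	THR1-LYS2	VIII	192	278	5	32.4	1.7	0.12	0.06	100
htz1	HIS4-CEN3	III	127	168	7	34.8	2.7	0.32	0.13	123
htz1	CEN3-MAT	III	181	125	2	22.2	1.9	0.22	0.16	115
htz1	MAT-RAD18	III	87	214	6	40.7	2.5	0.22	0.06	116
htz1	RAD18-HMR	III	180	129	0	20.9	1.4	NA	NA	101
htz1	SPO11-SPO13	VIII	114	176	14	42.8	3.5	0.57	0.17	103
htz1	SPO13-THR1	VIII	257	46	0	7.6	1.0	NA	NA	72
htz1	THR1-LYS2	VIII	119	180	2	31.9	1.9	0.07	0.05	98
hho1	HIS4-CEN3	III	215	290	5	31.4	1.6	0.13	0.06	111
hho1	CEN3-MAT	III	349	172	0	16.5	1.0	NA	NA	85
hho1	MAT-RAD18	III	186	312	15	39.2	2.3	0.30	0.09	112
hho1	RAD18-HMR	III	285	226	4	24.3	1.5	0.21	0.11	117
hho1	SPO11-SPO13	VIII	171	326	19	42.6	2.4	0.32	0.08	102
hho1	SPO13-THR1	VIII	391	107	1	11.3	1.1	0.30	0.30	107
hho1	THR1-LYS2	VIII	247	242	7	28.6	1.8	0.29	0.11	88
htz1_hho1	HIS4-CEN3	III	166	192	7	32.1	2.4	0.32	0.13	113
htz1_hho1	CEN3-MAT	III	211	154	2	22.6	1.7	0.17	0.12	117
htz1_hho1	MAT-RAD18	III	124	234	6	37.1	2.1	0.13	0.06	106
htz1_hho1	RAD18-HMR	III	195	158	5	26.3	2.2	0.38	0.18	126
htz1_hho1	SPO11-SPO13	VIII	125	220	18	45.2	3.3	0.51	0.14	109
htz1_hho1	SPO13-THR1	VIII	286	69	0	9.7	1.1	NA	NA	92
htz1_hho1	THR1-LYS2	VIII	167	186	1	27.1	1.5	0.05	0.05	84
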