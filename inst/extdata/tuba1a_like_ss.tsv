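chain	resnum	ss3
A	1	loop
A	2	helix
A	3	helix
A	4	loop
A	5	loop
A	6	loop
A	7	sheet
A	8	loop
A	9	helix
A	10	loop
A	11	loop
A	12	loop
A	13	loop
A	14	loop
A	15	loop
A	16	helix
A	17	sheet
A	18	helix
A	19	helix
A	20	sheet
A	21	loop
A	22	helix
A	23	loop
A	24	loop
A	25	loop
A	26	helix
A	27	loop
A	28	loop
A	29	loop
A	30	loop
A	31	loop
A	32	helix
A	33	helix
A	34	loop
A	35	loop
A	36	helix
A	37	helix
A	38	loop
A	39	loop
A	40	helix
A	41	helix
A	42	helix
A	43	helix
A	44	helix
A	45	loop
A	46	loop
A	47	sheet
A	48	loop
A	49	helix
A	50	loop
A	51	loop
A	52	loop
A	53	helix
A	54	helix
A	55	helix
A	56	helix
A	57	helix
A	58	sheet
A	59	sheet
A	60	sheet
A	61	loop
A	62	helix
A	63	loop
A	64	loop
A	65	loop
A	66	loop
A	67	helix
A	68	loop
A	69	helix
A	70	loop
A	71	loop
A	72	helix
A	73	loop
A	74	loop
A	75	helix
A	76	helix
A	77	loop
A	78	helix
A	79	helix
A	80	loop
A	81	sheet
A	82	helix
A	83	loop
A	84	helix
A	85	loop
A	86	helix
A	87	loop
A	88	helix
A	89	helix
A	90	loop
A	91	loop
A	92	loop
A	93	helix
A	94	loop
A	95	loop
A	96	helix
A	97	helix
A	98	sheet
A	99	loop
A	100	loop
A	101	helix
A	102	loop
A	103	loop
A	104	helix
A	105	loop
A	106	loop
A	107	loop
A	108	helix
A	109	loop
A	110	helix
A	111	helix
A	112	sheet
A	113	loop
A	114	helix
A	115	sheet
A	116	sheet
A	117	loop
A	118	sheet
A	119	helix
A	120	helix
A	121	helix
A	122	loop
A	123	helix
A	124	loop
A	125	loop
A	126	helix
A	127	loop
A	128	loop
A	129	helix
A	130	helix
A	131	loop
A	132	loop
A	133	loop
A	134	helix
A	135	loop
A	136	loop
A	137	loop
A	138	loop
A	139	loop
A	140	loop
A	141	loop
A	142	sheet
A	143	helix
A	144	loop
A	145	loop
A	146	loop
A	147	helix
A	148	loop
A	149	helix
A	150	loop
A	151	loop
A	152	helix
A	153	helix
A	154	sheet
A	155	helix
A	156	sheet
A	157	helix
A	158	loop
A	159	helix
A	160	helix
A	161	loop
A	162	helix
A	163	helix
A	164	loop
A	165	loop
A	166	helix
A	167	helix
A	168	helix
A	169	loop
A	170	sheet
A	171	loop
A	172	loop
A	173	sheet
A	174	helix
A	175	helix
A	176	loop
A	177	loop
A	178	loop
A	179	loop
A	180	loop
A	181	loop
A	182	sheet
A	183	helix
A	184	helix
A	185	helix
A	186	helix
A	187	loop
A	188	loop
A	189	loop
A	190	helix
A	191	loop
A	192	helix
A	193	loop
A	194	helix
A	195	loop
A	196	helix
A	197	loop
A	198	helix
A	199	loop
A	200	loop
A	201	loop
A	202	sheet
A	203	sheet
A	204	loop
A	205	helix
A	206	helix
A	207	loop
A	208	sheet
A	209	loop
A	210	helix
A	211	helix
A	212	loop
A	213	helix
A	214	sheet
A	215	helix
A	216	helix
A	217	helix
A	218	helix
A	219	helix
A	220	helix
A	221	helix
A	222	loop
A	223	loop
A	224	loop
A	225	helix
A	226	helix
A	227	loop
A	228	loop
A	229	sheet
A	230	helix
A	231	loop
A	232	helix
A	233	loop
A	234	loop
A	235	loop
A	236	helix
A	237	loop
A	238	sheet
A	239	loop
A	240	loop
A	241	helix
A	242	helix
A	243	helix
A	244	loop
A	245	sheet
A	246	loop
A	247	helix
A	248	loop
A	249	loop
A	250	loop
A	251	loop
A	252	loop
A	253	loop
A	254	loop
A	255	loop
A	256	loop
A	257	loop
A	258	helix
A	259	helix
A	260	loop
A	261	loop
A	262	helix
A	263	sheet
A	264	sheet
A	265	loop
A	266	helix
A	267	sheet
A	268	loop
A	269	helix
A	270	loop
A	271	helix
A	272	loop
A	273	helix
A	274	sheet
A	275	helix
A	276	loop
A	277	loop
A	278	loop
A	279	helix
A	280	sheet
A	281	helix
A	282	helix
A	283	helix
A	284	loop
A	285	loop
A	286	loop
A	287	helix
A	288	loop
A	289	helix
A	290	loop
A	291	helix
A	292	loop
A	293	helix
A	294	loop
A	295	sheet
A	296	helix
A	297	sheet
A	298	helix
A	299	helix
A	300	sheet
A	301	loop
A	302	helix
A	303	loop
A	304	loop
A	305	loop
A	306	helix
A	307	helix
A	308	loop
A	309	helix
A	310	helix
A	311	loop
A	312	loop
A	313	helix
A	314	loop
A	315	loop
A	316	helix
A	317	sheet
A	318	loop
A	319	helix
A	320	loop
A	321	helix
A	322	sheet
A	323	sheet
A	324	helix
A	325	helix
A	326	sheet
A	327	loop
A	328	loop
A	329	helix
A	330	loop
A	331	helix
A	332	helix
A	333	loop
A	334	helix
A	335	sheet
A	336	loop
A	337	helix
A	338	loop
A	339	sheet
A	340	helix
A	341	helix
A	342	loop
A	343	loop
A	344	loop
A	345	helix
A	346	loop
A	347	sheet
A	348	helix
A	349	helix
A	350	helix
A	351	helix
A	352	helix
A	353	sheet
A	354	loop
A	355	helix
A	356	helix
A	357	sheet
A	358	loop
A	359	helix
A	360	loop
A	361	loop
A	362	loop
A	363	loop
A	364	helix
A	365	loop
A	366	helix
A	367	loop
A	368	loop
A	369	helix
A	370	loop
A	371	loop
A	372	helix
A	373	loop
A	374	loop
A	375	sheet
A	376	helix
A	377	helix
A	378	helix
A	379	loop
A	380	helix
A	381	loop
A	382	loop
A	383	loop
A	384	loop
A	385	helix
A	386	helix
A	387	helix
A	388	loop
A	389	helix
A	390	loop
A	391	loop
A	392	loop
A	393	loop
A	394	loop
A	395	helix
A	396	loop
A	397	loop
A	398	loop
A	399	sheet
A	400	helix
A	401	loop
A	402	helix
A	403	loop
A	404	helix
A	405	loop
A	406	helix
A	407	loop
A	408	loop
A	409	sheet
A	410	helix
A	411	sheet
A	412	sheet
A	413	loop
A	414	loop
A	415	helix
A	416	helix
A	417	helix
A	418	helix
A	419	loop
A	420	loop
A	421	loop
A	422	helix
A	423	helix
A	424	loop
A	425	loop
A	426	loop
A	427	helix
A	428	loop
A	429	helix
A	430	helix
A	431	helix
A	432	loop
A	433	loop
A	434	loop
A	435	sheet
A	436	loop
A	437	sheet
A	438	loop
A	439	sheet
A	440	loop
A	441	loop
A	442	helix
A	443	sheet
A	444	sheet
A	445	helix
A	446	sheet
A	447	loop
A	448	loop
A	449	loop
A	450	loop
A	451	helix
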