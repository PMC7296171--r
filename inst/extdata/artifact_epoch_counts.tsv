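subject	mi_s1_train	mi_s1_test	mi_s2_train	mi_s2_test	erp_s1_train	erp_s1_test	erp_s1_test_chars	erp_s2_train	erp_s2_test	erp_s2_test_chars	ssvep_s1_train	ssvep_s1_test	ssvep_s2_train	ssvep_s2_test
s1	6	2	8	6	149	330	36	80	215	33	3	2	0	1
s2	2	0	0	1	95	5	5	38	115	25	0	0	0	0
s3	1	0	7	10	158	62	20	17	14	9	14	10	1	2
s4	0	0	0	0	32	34	14	7	10	4	9	18	0	0
s5	4	4	7	5	0	0	0	395	282	25	19	11	14	8
s6	4	2	4	3	159	113	24	171	146	29	25	26	5	6
s7	21	30	6	8	75	200	25	52	21	10	8	7	4	4
s8	2	0	4	1	427	325	32	35	87	22	3	2	9	5
s9	0	0	9	2	43	73	24	145	99	25	1	9	0	1
s10	0	2	0	0	94	15	6	61	78	20	0	0	2	4
s11	5	4	0	0	50	56	15	16	47	17	0	0	0	0
s12	0	16	2	6	75	94	22	98	185	31	0	1	1	7
s13	1	0	1	1	131	212	29	139	103	26	6	3	3	1
s14	1	0	2	1	18	35	11	234	190	32	4	6	13	22
s15	3	20	0	1	25	19	11	48	7	5	1	1	3	16
s16	0	2	13	10	492	322	33	113	92	19	0	0	8	9
s17	27	36	4	6	232	187	30	263	267	34	1	1	15	21
s18	1	11	13	9	166	404	31	92	122	29	3	2	2	4
s19	1	8	2	7	159	300	33	36	169	30	7	15	2	3
s20	0	7	1	1	236	240	34	112	323	35	2	2	1	2
s21	31	30	0	0	69	84	29	268	129	26	15	9	3	5
s22	2	8	2	0	131	128	32	11	48	18	9	2	0	1
s23	0	0	9	0	141	194	29	160	227	26	0	36	1	1
s24	0	1	8	4	65	106	27	87	158	31	2	1	1	5
s25	3	11	6	2	184	122	24	14	59	15	2	2	8	4
s26	0	1	0	0	447	552	36	196	265	32	20	22	7	6
s27	3	12	1	1	172	312	34	150	346	32	1	5	11	14
s28	2	6	0	0	93	63	21	37	52	19	6	4	2	1
s29	8	20	2	4	32	159	25	101	27	9	3	4	3	3
s30	3	9	4	0	141	171	34	38	30	14	0	1	0	0
s31	7	3	0	1	33	82	23	25	60	29	0	0	1	0
s32	33	67	0	2	122	339	33	80	32	13	13	34	19	21
s33	0	1	4	0	119	52	17	107	59	15	0	2	1	2
s34	32	18	8	19	254	181	33	142	441	35	13	21	18	16
s35	7	2	0	3	35	41	13	135	82	22	1	0	11	18
s36	3	2	6	17	178	189	34	110	159	32	3	4	0	4
s37	5	15	0	1	353	557	36	2	2	1	6	4	0	2
s38	11	8	0	0	194	119	29	53	29	10	17	11	11	11
s39	21	32	2	0	111	55	22	0	37	11	1	3	2	6
s40	1	2	1	0	145	206	33	11	56	16	31	26	3	7
s41	0	2	4	9	107	101	28	137	265	31	5	6	2	2
s42	0	0	9	10	121	191	31	35	62	19	10	15	10	2
s43	0	0	9	7	148	290	35	11	13	7	2	13	0	0
s44	3	7	3	13	293	392	35	32	76	25	10	7	7	0
s45	27	13	0	0	160	270	34	19	52	19	1	4	1	0
s46	0	1	6	11	226	307	35	52	175	34	1	4	2	4
s47	3	5	2	1	261	438	36	159	319	36	7	6	1	5
s48	6	1	0	2	25	52	18	41	35	13	2	5	20	12
s49	3	10	6	8	104	54	15	54	22	7	14	8	1	1
s50	23	48	4	9	48	229	24	2	0	0	0	0	5	6
s51	9	9	3	1	354	170	31	136	173	29	0	3	3	1
s52	0	0	2	1	20	74	23	57	139	31	3	8	0	2
s53	2	2	0	2	370	176	30	16	25	8	3	3	1	4
s54	3	14	1	0	149	107	18	66	51	17	7	6	7	4
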