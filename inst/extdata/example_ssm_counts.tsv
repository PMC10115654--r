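position	aa	boundCount	exprCount
1	A	249	160
1	R	33	213
1	N	183	364
1	D	143	286
1	C	112	57
1	Q	36	193
1	E	59	64
1	G	373	313
1	H	395	103
1	I	212	129
1	L	213	149
1	K	61	199
1	M	221	270
1	F	340	379
1	P	162	190
1	S	92	110
1	T	234	188
1	W	38	242
1	Y	44	314
1	V	289	285
2	A	46	193
2	R	38	101
2	N	5	219
2	D	322	129
2	C	362	253
2	Q	11	233
2	E	92	396
2	G	225	109
2	H	130	266
2	I	393	264
2	L	207	279
2	K	345	332
2	M	266	167
2	F	97	292
2	P	328	154
2	S	59	206
2	T	295	138
2	W	326	235
2	Y	391	345
2	V	375	189
3	A	187	122
3	R	262	66
3	N	243	285
3	D	208	145
3	C	388	317
3	Q	209	118
3	E	211	137
3	G	125	56
3	H	154	324
3	I	144	316
3	L	111	322
3	K	85	339
3	M	203	123
3	F	173	284
3	P	305	387
3	S	166	293
3	T	240	342
3	W	283	191
3	Y	90	98
3	V	91	220
4	A	293	89
4	R	317	79
4	N	276	393
4	D	303	242
4	C	101	50
4	Q	261	149
4	E	269	74
4	G	20	136
4	H	101	87
4	I	80	238
4	L	330	88
4	K	255	101
4	M	30	364
4	F	51	363
4	P	399	236
4	S	386	355
4	T	323	256
4	W	362	281
4	Y	70	186
4	V	283	269
5	A	258	244
5	R	347	70
5	N	183	377
5	D	170	207
5	C	223	397
5	Q	253	342
5	E	395	186
5	G	48	81
5	H	160	270
5	I	208	125
5	L	263	156
5	K	17	57
5	M	115	60
5	F	362	323
5	P	386	163
5	S	125	153
5	T	215	352
5	W	36	240
5	Y	198	158
5	V	172	161
6	A	16	390
6	R	391	388
6	N	109	186
6	D	140	389
6	C	318	396
6	Q	120	340
6	E	385	329
6	G	111	356
6	H	141	221
6	I	232	234
6	L	74	206
6	K	33	267
6	M	367	64
6	F	393	127
6	P	391	175
6	S	82	253
6	T	75	87
6	W	198	232
6	Y	252	325
6	V	364	263
7	A	38	349
7	R	259	239
7	N	358	218
7	D	284	373
7	C	195	147
7	Q	87	235
7	E	215	283
7	G	5	321
7	H	185	352
7	I	136	283
7	L	146	359
7	K	320	377
7	M	272	379
7	F	355	288
7	P	266	364
7	S	154	135
7	T	246	330
7	W	223	222
7	Y	342	51
7	V	93	247
8	A	376	343
8	R	231	206
8	N	168	278
8	D	244	346
8	C	233	136
8	Q	58	54
8	E	369	207
8	G	291	163
8	H	66	200
8	I	48	201
8	L	25	107
8	K	184	344
8	M	60	295
8	F	92	98
8	P	105	342
8	S	138	320
8	T	27	99
8	W	5	380
8	Y	201	242
8	V	81	247
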