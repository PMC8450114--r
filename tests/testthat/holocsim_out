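step	chromosome_length	avg_loop_length	frac_outside	n_side_by_side	state	replicate
0	20	0	0.96	10	sparse	1
5	20	9.2	0.776	10	sparse	1
10	20	16.6	0.628	10	sparse	1
15	20	22.8	0.504	10	sparse	1
20	20	27.8	0.404	10	sparse	1
25	18	28.2	0.412	9	sparse	1
30	18	32.2	0.352	9	sparse	1
35	18	34.4	0.328	9	sparse	1
40	18	38.4	0.268	9	sparse	1
45	18	41.6	0.224	9	sparse	1
50	18	43.6	0.204	9	sparse	1
55	18	45.4	0.188	9	sparse	1
60	18	46.4	0.188	9	sparse	1
65	18	47.4	0.188	9	sparse	1
70	18	48.2	0.188	9	sparse	1
75	18	48.4	0.188	9	sparse	1
80	18	48.4	0.188	9	sparse	1
85	18	48.4	0.188	9	sparse	1
90	18	48.4	0.188	9	sparse	1
95	18	48.4	0.188	9	sparse	1
100	18	48.4	0.188	9	sparse	1
105	18	48.4	0.188	9	sparse	1
110	18	48.4	0.188	9	sparse	1
115	18	48.4	0.188	9	sparse	1
120	18	48.4	0.188	9	sparse	1
125	18	48.4	0.188	9	sparse	1
130	18	48.4	0.188	9	sparse	1
135	18	48.4	0.188	9	sparse	1
140	18	48.4	0.188	9	sparse	1
145	16	44.9	0.262	8	sparse	1
150	16	46.4	0.252	8	sparse	1
155	16	47.9	0.242	8	sparse	1
160	16	49.4	0.232	8	sparse	1
165	16	50.6	0.222	8	compacted	1
170	16	51.6	0.212	8	compacted	1
175	16	52.6	0.202	8	compacted	1
180	16	53.6	0.192	8	compacted	1
185	16	54.3	0.188	8	compacted	1
190	16	54.8	0.188	8	compacted	1
195	16	55.3	0.188	8	compacted	1
200	16	55.8	0.188	8	compacted	1
205	16	56.3	0.188	8	compacted	1
210	16	56.8	0.188	8	compacted	1
215	16	57.3	0.188	8	compacted	1
220	16	57.8	0.188	8	compacted	1
225	16	58	0.188	8	compacted	1
230	16	58	0.188	8	compacted	1
235	16	58	0.188	8	compacted	1
240	16	58	0.188	8	compacted	1
245	16	58	0.188	8	compacted	1
250	16	58	0.188	8	compacted	1
255	16	58	0.188	8	compacted	1
260	16	58	0.188	8	compacted	1
265	16	58	0.188	8	compacted	1
270	16	58	0.188	8	compacted	1
275	16	58	0.188	8	compacted	1
280	16	58	0.188	8	compacted	1
285	16	58	0.188	8	compacted	1
290	16	58	0.188	8	compacted	1
295	16	58	0.188	8	compacted	1
300	16	58	0.188	8	compacted	1
305	16	58	0.188	8	compacted	1
310	16	58	0.188	8	compacted	1
315	16	58	0.188	8	compacted	1
320	16	58	0.188	8	compacted	1
325	16	58	0.188	8	compacted	1
330	16	58	0.188	8	compacted	1
335	16	58	0.188	8	compacted	1
340	16	58	0.188	8	compacted	1
345	16	58	0.188	8	compacted	1
350	16	58	0.188	8	compacted	1
355	16	58	0.188	8	compacted	1
360	16	58	0.188	8	compacted	1
365	16	58	0.188	8	compacted	1
370	16	58	0.188	8	compacted	1
375	16	58	0.188	8	compacted	1
380	16	58	0.188	8	compacted	1
385	16	58	0.188	8	compacted	1
390	16	58	0.188	8	compacted	1
395	16	58	0.188	8	compacted	1
400	16	58	0.188	8	compacted	1
405	16	58	0.188	8	compacted	1
410	16	58	0.188	8	compacted	1
415	16	58	0.188	8	compacted	1
420	16	58	0.188	8	compacted	1
425	16	58	0.188	8	compacted	1
430	16	58	0.188	8	compacted	1
435	16	58	0.188	8	compacted	1
440	16	58	0.188	8	compacted	1
445	16	58	0.188	8	compacted	1
450	16	58	0.188	8	compacted	1
455	16	58	0.188	8	compacted	1
460	16	58	0.188	8	compacted	1
465	16	58	0.188	8	compacted	1
470	16	58	0.188	8	compacted	1
475	16	58	0.188	8	compacted	1
480	16	58	0.188	8	compacted	1
485	16	58	0.188	8	compacted	1
490	16	58	0.188	8	compacted	1
495	16	58	0.188	8	compacted	1
500	16	49.2	0.364	8	sparse	1
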