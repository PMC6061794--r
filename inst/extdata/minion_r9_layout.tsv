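channel	row	col
1	1	1
2	2	1
3	3	1
4	4	1
5	5	1
6	6	1
7	7	1
8	8	1
9	9	1
10	10	1
11	11	1
12	12	1
13	13	1
14	14	1
15	15	1
16	16	1
17	1	2
18	2	2
19	3	2
20	4	2
21	5	2
22	6	2
23	7	2
24	8	2
25	9	2
26	10	2
27	11	2
28	12	2
29	13	2
30	14	2
31	15	2
32	16	2
33	1	3
34	2	3
35	3	3
36	4	3
37	5	3
38	6	3
39	7	3
40	8	3
41	9	3
42	10	3
43	11	3
44	12	3
45	13	3
46	14	3
47	15	3
48	16	3
49	1	4
50	2	4
51	3	4
52	4	4
53	5	4
54	6	4
55	7	4
56	8	4
57	9	4
58	10	4
59	11	4
60	12	4
61	13	4
62	14	4
63	15	4
64	16	4
65	1	5
66	2	5
67	3	5
68	4	5
69	5	5
70	6	5
71	7	5
72	8	5
73	9	5
74	10	5
75	11	5
76	12	5
77	13	5
78	14	5
79	15	5
80	16	5
81	1	6
82	2	6
83	3	6
84	4	6
85	5	6
86	6	6
87	7	6
88	8	6
89	9	6
90	10	6
91	11	6
92	12	6
93	13	6
94	14	6
95	15	6
96	16	6
97	1	7
98	2	7
99	3	7
100	4	7
101	5	7
102	6	7
103	7	7
104	8	7
105	9	7
106	10	7
107	11	7
108	12	7
109	13	7
110	14	7
111	15	7
112	16	7
113	1	8
114	2	8
115	3	8
116	4	8
117	5	8
118	6	8
119	7	8
120	8	8
121	9	8
122	10	8
123	11	8
124	12	8
125	13	8
126	14	8
127	15	8
128	16	8
129	1	9
130	2	9
131	3	9
132	4	9
133	5	9
134	6	9
135	7	9
136	8	9
137	9	9
138	10	9
139	11	9
140	12	9
141	13	9
142	14	9
143	15	9
144	16	9
145	1	10
146	2	10
147	3	10
148	4	10
149	5	10
150	6	10
151	7	10
152	8	10
153	9	10
154	10	10
155	11	10
156	12	10
157	13	10
158	14	10
159	15	10
160	16	10
161	1	11
162	2	11
163	3	11
164	4	11
165	5	11
166	6	11
167	7	11
168	8	11
169	9	11
170	10	11
171	11	11
172	12	11
173	13	11
174	14	11
175	15	11
176	16	11
177	1	12
178	2	12
179	3	12
180	4	12
181	5	12
182	6	12
183	7	12
184	8	12
185	9	12
186	10	12
187	11	12
188	12	12
189	13	12
190	14	12
191	15	12
192	16	12
193	1	13
194	2	13
195	3	13
196	4	13
197	5	13
198	6	13
199	7	13
200	8	13
201	9	13
202	10	13
203	11	13
204	12	13
205	13	13
206	14	13
207	15	13
208	16	13
209	1	14
210	2	14
211	3	14
212	4	14
213	5	14
214	6	14
215	7	14
216	8	14
217	9	14
218	10	14
219	11	14
220	12	14
221	13	14
222	14	14
223	15	14
224	16	14
225	1	15
226	2	15
227	3	15
228	4	15
229	5	15
230	6	15
231	7	15
232	8	15
233	9	15
234	10	15
235	11	15
236	12	15
237	13	15
238	14	15
239	15	15
240	16	15
241	1	16
242	2	16
243	3	16
244	4	16
245	5	16
246	6	16
247	7	16
248	8	16
249	9	16
250	10	16
251	11	16
252	12	16
253	13	16
254	14	16
255	15	16
256	16	16
257	1	17
258	2	17
259	3	17
260	4	17
261	5	17
262	6	17
263	7	17
264	8	17
265	9	17
266	10	17
267	11	17
268	12	17
269	13	17
270	14	17
271	15	17
272	16	17
273	1	18
274	2	18
275	3	18
276	4	18
277	5	18
278	6	18
279	7	18
280	8	18
281	9	18
282	10	18
283	11	18
284	12	18
285	13	18
286	14	18
287	15	18
288	16	18
289	1	19
290	2	19
291	3	19
292	4	19
293	5	19
294	6	19
295	7	19
296	8	19
297	9	19
298	10	19
299	11	19
300	12	19
301	13	19
302	14	19
303	15	19
304	16	19
305	1	20
306	2	20
307	3	20
308	4	20
309	5	20
310	6	20
311	7	20
312	8	20
313	9	20
314	10	20
315	11	20
316	12	20
317	13	20
318	14	20
319	15	20
320	16	20
321	1	21
322	2	21
323	3	21
324	4	21
325	5	21
326	6	21
327	7	21
328	8	21
329	9	21
330	10	21
331	11	21
332	12	21
333	13	21
334	14	21
335	15	21
336	16	21
337	1	22
338	2	22
339	3	22
340	4	22
341	5	22
342	6	22
343	7	22
344	8	22
345	9	22
346	10	22
347	11	22
348	12	22
349	13	22
350	14	22
351	15	22
352	16	22
353	1	23
354	2	23
355	3	23
356	4	23
357	5	23
358	6	23
359	7	23
360	8	23
361	9	23
362	10	23
363	11	23
364	12	23
365	13	23
366	14	23
367	15	23
368	16	23
369	1	24
370	2	24
371	3	24
372	4	24
373	5	24
374	6	24
375	7	24
376	8	24
377	9	24
378	10	24
379	11	24
380	12	24
381	13	24
382	14	24
383	15	24
384	16	24
385	1	25
386	2	25
387	3	25
388	4	25
389	5	25
390	6	25
391	7	25
392	8	25
393	9	25
394	10	25
395	11	25
396	12	25
397	13	25
398	14	25
399	15	25
400	16	25
401	1	26
402	2	26
403	3	26
404	4	26
405	5	26
406	6	26
407	7	26
408	8	26
409	9	26
410	10	26
411	11	26
412	12	26
413	13	26
414	14	26
415	15	26
416	16	26
417	1	27
418	2	27
419	3	27
420	4	27
421	5	27
422	6	27
423	7	27
424	8	27
425	9	27
426	10	27
427	11	27
428	12	27
429	13	27
430	14	27
431	15	27
432	16	27
433	1	28
434	2	28
435	3	28
436	4	28
437	5	28
438	6	28
439	7	28
440	8	28
441	9	28
442	10	28
443	11	28
444	12	28
445	13	28
446	14	28
447	15	28
448	16	28
449	1	29
450	2	29
451	3	29
452	4	29
453	5	29
454	6	29
455	7	29
456	8	29
457	9	29
458	10	29
459	11	29
460	12	29
461	13	29
462	14	29
463	15	29
464	16	29
465	1	30
466	2	30
467	3	30
468	4	30
469	5	30
470	6	30
471	7	30
472	8	30
473	9	30
474	10	30
475	11	30
476	12	30
477	13	30
478	14	30
479	15	30
480	16	30
481	1	31
482	2	31
483	3	31
484	4	31
485	5	31
486	6	31
487	7	31
488	8	31
489	9	31
490	10	31
491	11	31
492	12	31
493	13	31
494	14	31
495	15	31
496	16	31
497	1	32
498	2	32
499	3	32
500	4	32
501	5	32
502	6	32
503	7	32
504	8	32
505	9	32
506	10	32
507	11	32
508	12	32
509	13	32
510	14	32
511	15	32
512	16	32
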