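#id	S1-example
#voltage_mV	-120
index	class	duration_s	amplitude_pA
1	1	3.92660213801e-03	
2	0	3.55672985792e-05	
3	1	1.06552974021e-03	
4	0	4.76144636767e-05	
5	1	5.07000336817e-03	
6	0	2.01097686569e-04	
7	1	3.01983519161e-03	
8	0	7.55060213298e-05	
9	1	5.58250581879e-03	
10	0	2.01666227593e-04	
11	1	5.57929399366e-03	
12	0	1.17385434405e-04	
13	1	5.02336077674e-04	
14	0	3.49595286199e-04	
15	1	1.32983874890e-03	
16	0	1.11195869760e-04	
17	1	1.76937089362e-03	
18	0	1.25758976861e-04	
19	1	1.52035998030e-03	
20	0	3.92604480360e-04	
21	1	9.16613998859e-03	
22	0	1.77965197451e-04	
23	1	4.62501064036e-03	
24	0	7.44955036235e-04	
25	1	1.68024373585e-03	
26	0	2.02266341710e-05	
27	1	4.62949640972e-03	
28	0	1.52737150942e-06	
29	1	3.94512006305e-03	
30	0	3.88372704314e-04	
31	1	1.48126813305e-02	
32	0	2.31082917833e-04	
33	1	3.52545712250e-03	
34	0	1.08202297071e-05	
35	1	8.63855336301e-03	
36	0	8.58595987512e-04	
37	1	4.43152014393e-03	
38	0	7.06818325471e-04	
39	1	1.28888738522e-03	
40	0	7.50446137137e-04	
41	1	5.34893491789e-03	
42	0	1.30131853670e-05	
43	1	5.63669931116e-03	
44	0	7.81674378134e-04	
45	1	2.68866680249e-03	
46	0	4.28133662476e-04	
47	1	1.89561876018e-04	
48	0	1.34326850348e-04	
49	1	2.30674566355e-03	
50	0	1.06119526948e-04	
51	1	9.68244033415e-04	
52	0	3.17505089278e-04	
53	1	2.60615216077e-03	
54	0	1.15649297032e-05	
55	1	1.10543993182e-03	
56	0	5.36055383484e-07	
57	1	1.59016865636e-03	
58	0	1.21568966173e-04	
59	1	3.23102862050e-03	
60	0	2.10782152929e-05	
61	1	5.65884244298e-04	
62	0	2.23240265647e-03	
63	1	5.52171778174e-04	
64	0	2.52881932426e-04	
65	1	2.92999454599e-03	
66	0	3.16442235808e-06	
67	1	5.74965144634e-04	
68	0	7.52360170514e-05	
69	1	1.27119047719e-03	
70	0	4.24045897721e-06	
71	1	2.00866058829e-03	
72	0	8.23098607314e-05	
73	1	5.91032123443e-04	
74	0	6.45153182135e-06	
75	1	2.53239098627e-03	
76	0	8.62625880458e-05	
77	1	4.18818917773e-03	
78	0	6.59006030741e-05	
79	1	2.75019912628e-03	
80	0	8.83697578783e-04	
81	1	4.65999800410e-03	
82	0	9.36541673468e-05	
83	1	3.58179244349e-03	
84	0	3.54703587744e-04	
85	1	7.17739877207e-03	
86	0	1.49116810957e-04	
87	1	7.98868029198e-03	
88	0	8.53706212068e-06	
89	1	2.49257503184e-03	
90	0	5.24686457333e-05	
91	1	3.01580740005e-03	
92	0	2.22562982321e-04	
93	1	1.28863676666e-03	
94	0	1.49193471820e-04	
95	1	1.63176333562e-03	
96	0	4.57628776395e-04	
97	1	1.22012661042e-02	
98	0	2.82772955007e-04	
99	1	6.45434272959e-03	
100	0	1.34219118508e-05	
101	1	4.05565788956e-03	
102	0	1.20231427869e-04	
103	1	3.86623665076e-03	
104	0	1.20539310526e-05	
105	1	3.37790428377e-03	
106	0	1.02579296992e-03	
107	1	9.40069024481e-04	
108	0	2.75786098775e-03	
109	1	1.68493747741e-03	
110	0	1.05750214367e-04	
111	1	1.09655006729e-03	
112	0	1.24816916648e-03	
113	1	5.35000108386e-03	
114	0	2.26420730827e-04	
115	1	1.55796235908e-03	
116	0	5.06305178145e-05	
117	1	4.56479087205e-03	
118	0	1.28125456170e-04	
119	1	4.18219736974e-03	
120	0	2.45907096830e-06	
121	1	2.18727771013e-03	
122	0	2.04919787863e-04	
123	1	3.44921854581e-03	
124	0	3.38717204800e-04	
125	1	9.32009809572e-03	
126	0	1.54611762068e-04	
127	1	5.46086942450e-03	
128	0	9.73978635394e-04	
129	1	1.32772384602e-03	
130	0	1.87960102553e-04	
131	1	2.97936157220e-03	
132	0	3.66439374116e-04	
133	1	8.89189711081e-04	
134	0	9.50853960456e-05	
135	1	7.99981149271e-04	
136	0	3.60923133917e-04	
137	1	1.32003555435e-03	
138	0	1.20909257034e-03	
139	1	1.87424066807e-03	
140	0	6.54421609405e-04	
141	1	4.60524879249e-03	
142	0	6.14542706797e-04	
143	1	2.00740361977e-03	
144	0	3.20025473867e-05	
145	1	6.36293474678e-03	
146	0	4.31436637186e-05	
147	1	1.78840404917e-04	
148	0	7.47688102835e-04	
149	1	5.29480441897e-03	
150	0	3.70342440543e-06	
151	1	1.48582041654e-03	
152	0	6.76230191105e-04	
153	1	3.30177529912e-03	
154	0	9.52268247154e-04	
155	1	7.69316789398e-04	
156	0	3.49133664046e-04	
157	1	2.55229739977e-03	
158	0	4.56421767875e-06	
159	1	3.58227386743e-04	
160	0	4.07266715481e-05	
161	1	6.80695753545e-05	
162	0	7.76465578425e-05	
163	1	5.84031858354e-05	
164	0	9.28644953603e-05	
165	1	8.32274871608e-04	
166	0	1.20296570557e-05	
167	1	1.95069342040e-03	
168	0	9.48506415755e-04	
169	1	2.08123659475e-03	
170	0	3.07791326354e-05	
171	1	1.84420059705e-03	
172	0	6.00598481545e-05	
173	1	7.98103901287e-04	
174	0	8.74274302765e-04	
175	1	1.25855823017e-03	
176	0	2.09240611658e-04	
177	1	9.68913300607e-04	
178	0	1.12797132017e-05	
179	1	6.79361231385e-04	
180	0	2.85954919474e-05	
181	1	5.73246622010e-03	
182	0	2.50586015119e-05	
183	1	1.07945258093e-02	
184	0	3.55246634519e-05	
185	1	3.10526020071e-03	
186	0	3.76071576425e-04	
187	1	5.80279616191e-03	
188	0	7.14584875893e-05	
189	1	6.34034658124e-03	
190	0	3.26982378353e-04	
191	1	9.42592988544e-04	
192	0	7.24204328200e-04	
193	1	4.83409531027e-03	
194	0	2.42079432334e-04	
195	1	6.38380170529e-04	
196	0	1.26389566146e-04	
197	1	6.23166365828e-04	
198	0	5.26218787764e-05	
199	1	2.18005522094e-03	
200	0	5.28384685197e-06	
201	1	3.46412462135e-04	
202	0	5.87063894082e-05	
203	1	1.52927647615e-04	
204	0	8.86247763151e-05	
205	1	9.95181612070e-04	
206	0	5.97388985618e-04	
207	1	2.88317485609e-03	
208	0	4.45726856759e-07	
209	1	2.30485275422e-03	
210	0	9.50597599101e-05	
211	1	2.33629202877e-03	
212	0	7.25025086214e-04	
213	1	4.52524988374e-03	
214	0	4.98529047367e-06	
215	1	5.17714517464e-03	
216	0	1.14566838193e-03	
217	1	5.12687608059e-04	
218	0	1.16327222043e-03	
219	1	5.15311343508e-03	
220	0	7.14084324920e-06	
221	1	2.17198696318e-03	
222	0	1.79457604668e-04	
223	1	8.46108711595e-04	
224	0	1.39571473310e-06	
225	1	2.14229624779e-03	
226	0	1.55142715342e-04	
227	1	7.48493373899e-04	
228	0	2.00998550586e-04	
229	1	1.19778327193e-03	
230	0	1.46659628213e-05	
231	1	4.08797801947e-04	
232	0	1.67623576598e-04	
233	1	9.17469753874e-03	
234	0	1.05986202935e-04	
235	1	4.75701859095e-04	
236	0	3.65725828252e-04	
237	1	4.55856160384e-03	
238	0	2.58083998183e-05	
239	1	7.59831534117e-03	
240	0	6.03872006563e-04	
241	1	1.01383903154e-03	
242	0	4.16645365320e-05	
243	1	3.71902173432e-03	
244	0	5.14666559362e-05	
245	1	1.01889453127e-03	
246	0	5.91283219740e-05	
247	1	7.58295247787e-04	
248	0	1.92123367103e-04	
249	1	8.19207722461e-03	
250	0	4.01951362040e-07	
251	1	1.00024471720e-03	
252	0	4.32599798371e-05	
253	1	1.45523256112e-04	
254	0	3.32119448947e-05	
255	1	4.37327795198e-03	
256	0	6.35429090829e-04	
257	1	9.79213156954e-03	
258	0	6.56248118901e-05	
259	1	8.57902674245e-04	
260	0	2.02262723840e-05	
261	1	5.23552275228e-03	
262	0	2.72434588987e-05	
263	1	2.61034179599e-04	
264	0	3.68158670873e-05	
265	1	7.68551506811e-04	
266	0	1.16295206426e-05	
267	1	3.36270031192e-04	
268	0	3.86310156318e-05	
269	1	2.68034253917e-03	
270	0	2.10821412648e-04	
271	1	1.02685055336e-03	
272	0	3.46190075331e-04	
273	1	3.84416144568e-03	
274	0	1.68691294075e-04	
275	1	1.08609356702e-02	
276	0	3.85259919461e-05	
277	1	9.43974219263e-04	
278	0	4.26055685670e-04	
279	1	3.52986242248e-03	
280	0	1.69870946345e-06	
281	1	5.42457105424e-04	
282	0	5.53366145365e-05	
283	1	6.46252855058e-04	
284	0	3.92739876904e-04	
285	1	3.83689544462e-03	
286	0	2.07736342244e-04	
287	1	5.22394875458e-03	
288	0	1.76350046637e-05	
289	1	1.28504847134e-03	
290	0	2.56565549220e-05	
291	1	2.72865882626e-03	
292	0	3.01112518752e-06	
293	1	2.42221356456e-03	
294	0	1.05967359616e-04	
295	1	8.01767411811e-03	
296	0	7.46750283783e-04	
297	1	1.38515165442e-03	
298	0	6.18375555046e-05	
299	1	6.34714264035e-03	
300	0	8.00025379497e-06	
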