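index	label	abbrev	hemisphere	name	division
1	PreC.L	PreC	L	Precentral gyrus	cerebrum
2	PreC.R	PreC	R	Precentral gyrus	cerebrum
3	ACG.L	ACG	L	Anterior cingulate and paracingulate gyri	cerebrum
4	ACG.R	ACG	R	Anterior cingulate and paracingulate gyri	cerebrum
5	AMYG.L	AMYG	L	Amygdala	cerebrum
6	AMYG.R	AMYG	R	Amygdala	cerebrum
7	ANG.L	ANG	L	Angular gyrus	cerebrum
8	ANG.R	ANG	R	Angular gyrus	cerebrum
9	CAL.L	CAL	L	Calcarine fissure and surrounding cortex	cerebrum
10	CAL.R	CAL	R	Calcarine fissure and surrounding cortex	cerebrum
11	CAU.L	CAU	L	Caudate nucleus	cerebrum
12	CAU.R	CAU	R	Caudate nucleus	cerebrum
13	CUN.L	CUN	L	Cuneus	cerebrum
14	CUN.R	CUN	R	Cuneus	cerebrum
15	DCG.L	DCG	L	Median cingulate and paracingulate gyri	cerebrum
16	DCG.R	DCG	R	Median cingulate and paracingulate gyri	cerebrum
17	FFG.L	FFG	L	Fusiform gyrus	cerebrum
18	FFG.R	FFG	R	Fusiform gyrus	cerebrum
19	HES.L	HES	L	Heschl gyrus	cerebrum
20	HES.R	HES	R	Heschl gyrus	cerebrum
21	HIP.L	HIP	L	Hippocampus	cerebrum
22	HIP.R	HIP	R	Hippocampus	cerebrum
23	IFGoper.L	IFGoper	L	Inferior frontal gyrus (opercular part)	cerebrum
24	IFGoper.R	IFGoper	R	Inferior frontal gyrus (opercular part)	cerebrum
25	IFGtriang.L	IFGtriang	L	Inferior frontal gyrus (triangular part)	cerebrum
26	IFGtriang.R	IFGtriang	R	Inferior frontal gyrus (triangular part)	cerebrum
27	INS.L	INS	L	Insula	cerebrum
28	INS.R	INS	R	Insula	cerebrum
29	IOG.L	IOG	L	Inferior occipital gyrus	cerebrum
30	IOG.R	IOG	R	Inferior occipital gyrus	cerebrum
31	IPL.L	IPL	L	Inferior parietal gyrus	cerebrum
32	IPL.R	IPL	R	Inferior parietal gyrus	cerebrum
33	ITG.L	ITG	L	Inferior temporal gyrus	cerebrum
34	ITG.R	ITG	R	Inferior temporal gyrus	cerebrum
35	LING.L	LING	L	Lingual gyrus	cerebrum
36	LING.R	LING	R	Lingual gyrus	cerebrum
37	MFG.L	MFG	L	Middle frontal gyrus	cerebrum
38	MFG.R	MFG	R	Middle frontal gyrus	cerebrum
39	MOG.L	MOG	L	Middle occipital gyrus	cerebrum
40	MOG.R	MOG	R	Middle occipital gyrus	cerebrum
41	MTG.L	MTG	L	Middle temporal gyrus	cerebrum
42	MTG.R	MTG	R	Middle temporal gyrus	cerebrum
43	OLF.L	OLF	L	Olfactory cortex	cerebrum
44	OLF.R	OLF	R	Olfactory cortex	cerebrum
45	ORBinf.L	ORBinf	L	Inferior frontal gyrus (orbital part)	cerebrum
46	ORBinf.R	ORBinf	R	Inferior frontal gyrus (orbital part)	cerebrum
47	ORBmid.L	ORBmid	L	Middle frontal gyrus (orbital part)	cerebrum
48	ORBmid.R	ORBmid	R	Middle frontal gyrus (orbital part)	cerebrum
49	ORBsup.L	ORBsup	L	Superior frontal gyrus (orbital part)	cerebrum
50	ORBsup.R	ORBsup	R	Superior frontal gyrus (orbital part)	cerebrum
51	ORBsupmed.L	ORBsupmed	L	Superior frontal gyrus (medial orbital)	cerebrum
52	ORBsupmed.R	ORBsupmed	R	Superior frontal gyrus (medial orbital)	cerebrum
53	PAL.L	PAL	L	Lenticular nucleus, pallidum	cerebrum
54	PAL.R	PAL	R	Lenticular nucleus, pallidum	cerebrum
55	PCL.L	PCL	L	Paracentral lobule	cerebrum
56	PCL.R	PCL	R	Paracentral lobule	cerebrum
57	PCG.L	PCG	L	Posterior cingulate gyrus	cerebrum
58	PCG.R	PCG	R	Posterior cingulate gyrus	cerebrum
59	PCUN.L	PCUN	L	Precuneus	cerebrum
60	PCUN.R	PCUN	R	Precuneus	cerebrum
61	PHG.L	PHG	L	Parahippocampal gyrus	cerebrum
62	PHG.R	PHG	R	Parahippocampal gyrus	cerebrum
63	PostC.L	PostC	L	Postcentral gyrus	cerebrum
64	PostC.R	PostC	R	Postcentral gyrus	cerebrum
65	PUT.L	PUT	L	Lenticular nucleus, putamen	cerebrum
66	PUT.R	PUT	R	Lenticular nucleus, putamen	cerebrum
67	REC.L	REC	L	Rectus gyrus	cerebrum
68	REC.R	REC	R	Rectus gyrus	cerebrum
69	ROL.L	ROL	L	Rolandic operculum	cerebrum
70	ROL.R	ROL	R	Rolandic operculum	cerebrum
71	SFGdor.L	SFGdor	L	Superior frontal gyrus (dorsolateral)	cerebrum
72	SFGdor.R	SFGdor	R	Superior frontal gyrus (dorsolateral)	cerebrum
73	SFGmed.L	SFGmed	L	Superior frontal gyrus (medial)	cerebrum
74	SFGmed.R	SFGmed	R	Superior frontal gyrus (medial)	cerebrum
75	SMA.L	SMA	L	Supplementary motor area	cerebrum
76	SMA.R	SMA	R	Supplementary motor area	cerebrum
77	SMG.L	SMG	L	Supramarginal gyrus	cerebrum
78	SMG.R	SMG	R	Supramarginal gyrus	cerebrum
79	SOG.L	SOG	L	Superior occipital gyrus	cerebrum
80	SOG.R	SOG	R	Superior occipital gyrus	cerebrum
81	SPG.L	SPG	L	Superior parietal gyrus	cerebrum
82	SPG.R	SPG	R	Superior parietal gyrus	cerebrum
83	STG.L	STG	L	Superior temporal gyrus	cerebrum
84	STG.R	STG	R	Superior temporal gyrus	cerebrum
85	THA.L	THA	L	Thalamus	cerebrum
86	THA.R	THA	R	Thalamus	cerebrum
87	TPOmid.L	TPOmid	L	Temporal pole: middle temporal gyrus	cerebrum
88	TPOmid.R	TPOmid	R	Temporal pole: middle temporal gyrus	cerebrum
89	TPOsup.L	TPOsup	L	Temporal pole: superior temporal gyrus	cerebrum
90	TPOsup.R	TPOsup	R	Temporal pole: superior temporal gyrus	cerebrum
91	Crus1.L	Crus1	L	Crus cerebelli I	cerebellum
92	Crus1.R	Crus1	R	Crus cerebelli I	cerebellum
93	Crus2.L	Crus2	L	Crus cerebelli II	cerebellum
94	Crus2.R	Crus2	R	Crus cerebelli II	cerebellum
95	CL3.L	CL3	L	Cerebellar lobule III	cerebellum
96	CL3.R	CL3	R	Cerebellar lobule III	cerebellum
97	CL4_5.L	CL4_5	L	Cerebellar lobule IV/V	cerebellum
98	CL4_5.R	CL4_5	R	Cerebellar lobule IV/V	cerebellum
99	CL6.L	CL6	L	Cerebellar lobule VI	cerebellum
100	CL6.R	CL6	R	Cerebellar lobule VI	cerebellum
101	CL7b.L	CL7b	L	Cerebellar lobule VIIB	cerebellum
102	CL7b.R	CL7b	R	Cerebellar lobule VIIB	cerebellum
103	CL8.L	CL8	L	Cerebellar lobule VIII	cerebellum
104	CL8.R	CL8	R	Cerebellar lobule VIII	cerebellum
105	CL9.L	CL9	L	Cerebellar lobule IX	cerebellum
106	CL9.R	CL9	R	Cerebellar lobule IX	cerebellum
107	CL10.L	CL10	L	Cerebellar lobule X	cerebellum
108	CL10.R	CL10	R	Cerebellar lobule X	cerebellum
109	Vr1_2	Vr1_2	M	Vermis lobule I/II	cerebellum
110	Vr3	Vr3	M	Vermis lobule III	cerebellum
111	Vr4_5	Vr4_5	M	Vermis lobule IV/V	cerebellum
112	Vr6	Vr6	M	Vermis lobule VI	cerebellum
113	Vr7	Vr7	M	Vermis lobule VII	cerebellum
114	Vr8	Vr8	M	Vermis lobule VIII	cerebellum
115	Vr9	Vr9	M	Vermis lobule IX	cerebellum
116	Vr10	Vr10	M	Vermis lobule X	cerebellum
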