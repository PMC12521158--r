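index	label	hemisphere	region
1	PreCG.L	L	Precentral gyrus, left
2	PreCG.R	R	Precentral gyrus, right
3	SFGdor.L	L	Superior frontal gyrus, dorsolateral, left
4	SFGdor.R	R	Superior frontal gyrus, dorsolateral, right
5	ORBsup.L	L	Superior frontal gyrus, orbital part, left
6	ORBsup.R	R	Superior frontal gyrus, orbital part, right
7	MFG.L	L	Middle frontal gyrus, left
8	MFG.R	R	Middle frontal gyrus, right
9	ORBmid.L	L	Middle frontal gyrus, orbital part, left
10	ORBmid.R	R	Middle frontal gyrus, orbital part, right
11	IFGoperc.L	L	Inferior frontal gyrus, opercular part, left
12	IFGoperc.R	R	Inferior frontal gyrus, opercular part, right
13	IFGtriang.L	L	Inferior frontal gyrus, triangular part, left
14	IFGtriang.R	R	Inferior frontal gyrus, triangular part, right
15	ORBinf.L	L	Inferior frontal gyrus, orbital part, left
16	ORBinf.R	R	Inferior frontal gyrus, orbital part, right
17	ROL.L	L	Rolandic operculum, left
18	ROL.R	R	Rolandic operculum, right
19	SMA.L	L	Supplementary motor area, left
20	SMA.R	R	Supplementary motor area, right
21	OLF.L	L	Olfactory cortex, left
22	OLF.R	R	Olfactory cortex, right
23	SFGmed.L	L	Superior frontal gyrus, medial, left
24	SFGmed.R	R	Superior frontal gyrus, medial, right
25	ORBsupmed.L	L	Superior frontal gyrus, medial orbital, left
26	ORBsupmed.R	R	Superior frontal gyrus, medial orbital, right
27	REC.L	L	Gyrus rectus, left
28	REC.R	R	Gyrus rectus, right
29	INS.L	L	Insula, left
30	INS.R	R	Insula, right
31	ACG.L	L	Anterior cingulate gyrus, left
32	ACG.R	R	Anterior cingulate gyrus, right
33	DCG.L	L	Median cingulate gyrus, left
34	DCG.R	R	Median cingulate gyrus, right
35	PCG.L	L	Posterior cingulate gyrus, left
36	PCG.R	R	Posterior cingulate gyrus, right
37	HIP.L	L	Hippocampus, left
38	HIP.R	R	Hippocampus, right
39	PHG.L	L	Parahippocampal gyrus, left
40	PHG.R	R	Parahippocampal gyrus, right
41	AMYG.L	L	Amygdala, left
42	AMYG.R	R	Amygdala, right
43	CAL.L	L	Calcarine fissure and surrounding cortex, left
44	CAL.R	R	Calcarine fissure and surrounding cortex, right
45	CUN.L	L	Cuneus, left
46	CUN.R	R	Cuneus, right
47	LING.L	L	Lingual gyrus, left
48	LING.R	R	Lingual gyrus, right
49	SOG.L	L	Superior occipital gyrus, left
50	SOG.R	R	Superior occipital gyrus, right
51	MOG.L	L	Middle occipital gyrus, left
52	MOG.R	R	Middle occipital gyrus, right
53	IOG.L	L	Inferior occipital gyrus, left
54	IOG.R	R	Inferior occipital gyrus, right
55	FFG.L	L	Fusiform gyrus, left
56	FFG.R	R	Fusiform gyrus, right
57	PoCG.L	L	Postcentral gyrus, left
58	PoCG.R	R	Postcentral gyrus, right
59	SPG.L	L	Superior parietal gyrus, left
60	SPG.R	R	Superior parietal gyrus, right
61	IPL.L	L	Inferior parietal lobule, left
62	IPL.R	R	Inferior parietal lobule, right
63	SMG.L	L	Supramarginal gyrus, left
64	SMG.R	R	Supramarginal gyrus, right
65	ANG.L	L	Angular gyrus, left
66	ANG.R	R	Angular gyrus, right
67	PCUN.L	L	Precuneus, left
68	PCUN.R	R	Precuneus, right
69	PCL.L	L	Paracentral lobule, left
70	PCL.R	R	Paracentral lobule, right
71	CAU.L	L	Caudate nucleus, left
72	CAU.R	R	Caudate nucleus, right
73	PUT.L	L	Putamen, left
74	PUT.R	R	Putamen, right
75	PAL.L	L	Pallidum, left
76	PAL.R	R	Pallidum, right
77	THA.L	L	Thalamus, left
78	THA.R	R	Thalamus, right
79	HES.L	L	Heschl gyrus, left
80	HES.R	R	Heschl gyrus, right
81	STG.L	L	Superior temporal gyrus, left
82	STG.R	R	Superior temporal gyrus, right
83	TPOsup.L	L	Temporal pole: superior temporal gyrus, left
84	TPOsup.R	R	Temporal pole: superior temporal gyrus, right
85	MTG.L	L	Middle temporal gyrus, left
86	MTG.R	R	Middle temporal gyrus, right
87	TPOmid.L	L	Temporal pole: middle temporal gyrus, left
88	TPOmid.R	R	Temporal pole: middle temporal gyrus, right
89	ITG.L	L	Inferior temporal gyrus, left
90	ITG.R	R	Inferior temporal gyrus, right
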