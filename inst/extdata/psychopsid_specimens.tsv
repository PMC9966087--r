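specimen_no	repository_id	epoch	provenance	included_in_analysis	body_length_mm	length_is_estimate	labrum_morphotype	notes
1		Cretaceous	prior_study	TRUE			unknown	
2		Cretaceous	prior_study	TRUE			unknown	
3		Cretaceous	prior_study	TRUE			unknown	
4		Cretaceous	prior_study	TRUE			unknown	
5		Cretaceous	prior_study	TRUE			unknown	
6		Cretaceous	prior_study	TRUE			unknown	
7		Cretaceous	prior_study	TRUE			unknown	
8		Cretaceous	prior_study	TRUE			unknown	
9		Cretaceous	prior_study	TRUE			unknown	
10		Cretaceous	prior_study	TRUE			unknown	
11		Cretaceous	prior_study	TRUE			unknown	
12		Cretaceous	prior_study	TRUE			unknown	
13		Cretaceous	prior_study	TRUE			unknown	
14		Cretaceous	prior_study	TRUE			unknown	
15		Cretaceous	prior_study	TRUE			unknown	
16		Cretaceous	prior_study	TRUE			unknown	
17		Cretaceous	prior_study	TRUE			unknown	
18		Cretaceous	prior_study	TRUE			unknown	
19		Cretaceous	prior_study	TRUE			unknown	
20		Cretaceous	prior_study	TRUE			unknown	
21		Cretaceous	prior_study	TRUE			unknown	
22		Cretaceous	prior_study	TRUE			unknown	
23		Cretaceous	prior_study	TRUE			unknown	
24		Cretaceous	prior_study	TRUE			unknown	
25		Cretaceous	prior_study	TRUE			unknown	
26		Cretaceous	prior_study	TRUE			unknown	
27		Cretaceous	prior_study	TRUE			unknown	
28		Cretaceous	prior_study	TRUE			unknown	
29		Eocene	prior_study	TRUE			unknown	
30		Eocene	prior_study	TRUE			unknown	
31		Eocene	prior_study	TRUE			unknown	
32		Eocene	prior_study	TRUE			unknown	
33		Eocene	prior_study	TRUE			unknown	
34		Eocene	prior_study	TRUE			unknown	
35		Eocene	prior_study	TRUE			unknown	
36		Eocene	prior_study	TRUE			unknown	
37		Eocene	prior_study	TRUE			unknown	
38		Eocene	prior_study	TRUE			unknown	
39		Eocene	prior_study	TRUE			unknown	
40		Eocene	prior_study	TRUE			unknown	
41		extant	prior_study	TRUE			unknown	
42		extant	prior_study	TRUE			unknown	
43		extant	prior_study	TRUE			unknown	
44		extant	prior_study	TRUE			unknown	
45		extant	prior_study	TRUE			unknown	
46		extant	prior_study	TRUE			unknown	
47		extant	prior_study	TRUE			unknown	
48		extant	prior_study	TRUE			unknown	
49		extant	prior_study	TRUE			unknown	
50		extant	prior_study	TRUE			unknown	
51		extant	prior_study	TRUE			unknown	
52		extant	prior_study	TRUE			unknown	
53	PED 0150	Cretaceous	this_study	FALSE	3.6	FALSE	unknown	head turned or deformed; labrum partly concealed
54	PED 0267	Cretaceous	this_study	FALSE	14	TRUE	unknown	head capsule only; rim and labrum concealed by debris
55	PED 0322	Cretaceous	this_study	FALSE	3.9	FALSE	triangular	head accessible in lateral view only
56	PED 0379	Cretaceous	this_study	TRUE	5.5	FALSE	pentadent	five prongs: large middle spine flanked by two smaller on each side
57	PED 0382	Cretaceous	this_study	TRUE	8.6	FALSE	trident	
58	PED 0389	Cretaceous	this_study	TRUE	9.9	FALSE	trident	
59	PED 0412	Cretaceous	this_study	TRUE	2.8	FALSE	broad	broad pentagonal labrum with small spine-like corner elevations
60	PED 0430	Cretaceous	this_study	TRUE	3.6	FALSE	trident_bifid	large bifurcated middle spine
61	PED 0440	Cretaceous	this_study	TRUE	1.2	FALSE	unknown	labrum triangular to pentagonal in dorsal view
62	PED 0456	Cretaceous	this_study	TRUE	1.5	FALSE	unknown	trapezoidal labrum with large V-shaped distal split
63	PED 0535	Cretaceous	this_study	TRUE	1.8	FALSE	triangular	
64	PED 0584	Cretaceous	this_study	FALSE	3.3	TRUE	unknown	strongly verlumt; head and partial thorax only
65	PED 0612	Cretaceous	this_study	TRUE	6.9	FALSE	trident	
66	PED 0621	Cretaceous	this_study	TRUE	5.7	FALSE	trident	
67	PED 0625	Cretaceous	this_study	FALSE	14.1	TRUE	trident	head only; ventral side partly ground off
68	PED 0662	Cretaceous	this_study	TRUE	8.3	FALSE	broad	labrum mostly concealed but relatively broad and short
69	PED 0751	Cretaceous	this_study	TRUE	9.85	TRUE	trident	measured length approximately 5.0 mm
70	PED 0774	Cretaceous	this_study	TRUE	2.6	TRUE	triangular	
71	PED 0845	Cretaceous	this_study	FALSE	15.7	FALSE	unknown	strongly concealed; head turned or deformed
72	PED 0932	Cretaceous	this_study	TRUE	5.65	TRUE	trident_bifid	large bifurcated middle spine
73	PED 0998	Cretaceous	this_study	TRUE	10.5	FALSE	triangular	triangular labrum with shallow distal cleft
74	PED 1049	Cretaceous	this_study	TRUE	7.6	TRUE	trident	head, neck and partial prothorax only
75	PED 1459	Cretaceous	this_study	TRUE	2	FALSE	triangular	
76	PED 1627	Cretaceous	this_study	TRUE	10.1	FALSE	broad	labrum relatively broad, short and pentagonal
77	PED 1666	Cretaceous	this_study	TRUE	1.9	FALSE	unknown	labrum triangular to pentagonal; fan-like setae
78	PED 1703	Cretaceous	this_study	TRUE	2.9	FALSE	pentagonal	pentagonal, well rounded labrum
79	PED 1726	Cretaceous	this_study	TRUE	10.6	TRUE	broad	measured length approximately 7.6 mm; broad short labrum with broad distal cleft
80	PED 1732	Cretaceous	this_study	TRUE	7.7	FALSE	broad	broad pentagonal labrum with small spine-like corner elevations
81	PED 1813	Cretaceous	this_study	TRUE	3.5	FALSE	unknown	almost square labrum, one bigger middle cleft and two flanking clefts
82	PED 1831	Cretaceous	this_study	TRUE	3.25	TRUE	triangular	head, neck and partial prothorax only
83	PED 1846	Cretaceous	this_study	TRUE	4.1	TRUE	unknown	almost square labrum, one bigger middle cleft and two flanking clefts
84	PED 1884	Cretaceous	this_study	TRUE	3.4	FALSE	trident_bifid	large bifurcated middle spine
85	PED 1887	Cretaceous	this_study	FALSE	4.5	TRUE	broad	head separated from body; neck region missing
86	PED 1928	Cretaceous	this_study	TRUE	6.2	TRUE	trident_bifid	measured length approximately 4.0 mm
87	PED 1940	Cretaceous	this_study	TRUE	2.55	TRUE	triangular	measured length approximately 1.3 mm
88	PED 1967	Cretaceous	this_study	TRUE	11.9	FALSE	trident	
89	PED 2056	Cretaceous	this_study	TRUE	4.1	FALSE	triangular	labrum triangular symmetric to trapezium-like, elongated
90	PED 2171	Cretaceous	this_study	TRUE	2.6	FALSE	triangular	labrum triangular symmetric to trapezium-like, elongated
91	PED 2309	Cretaceous	this_study	TRUE	2.2	FALSE	triangular	labrum triangular symmetric to trapezium-like, elongated
92	PED 2311	Cretaceous	this_study	TRUE	1.3	FALSE	triangular	labrum triangular symmetric to trapezium-like, very elongated
93	PED 2329	Cretaceous	this_study	TRUE	1.8	FALSE	pentagonal	head only; labrum pentagonal, relatively broad
94	PED 2446	Cretaceous	this_study	TRUE	2	FALSE	triangular	head only; labrum triangular, relatively elongated
95	PED 2448	Cretaceous	this_study	FALSE	5	FALSE	unknown	largely concealed by dirt; only rough outline apparent
96	PED 2432	Cretaceous	this_study	TRUE	8.5	FALSE	unknown	labrum simple triangular to pentagonal
97		Eocene	this_study	FALSE	3	TRUE	unknown	known only from a small literature photograph with a bubble concealing the body; assumed excluded
98		Eocene	this_study	TRUE		FALSE	unknown	studied from photographs; assumed to enter head-based analyses only
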