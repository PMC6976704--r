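index	partition	n_states	description
1	adult_body	2	Arista, microtrichia length
2	adult_body	2	Male arista, microtrichia
3	adult_body	2	Arista, development
4	adult_body	2	Arista, setae
5	adult_body	2	Arista, thickening
6	adult_body	3	First aristomere, length
7	adult_body	2	Lunule, setae
8	adult_body	2	Female, groove between fronto-orbital plate and parafacial
9	adult_body	3	Male, proclinate orbital setae
10	adult_body	3	Female, proclinate orbital setae
11	adult_body	2	Proclinate orbital setae, when present, number
12	adult_body	2	Vibrissal triangle
13	adult_body	2	Shape of lower facial margin, shape
14	adult_body	2	Facial plate, shape
15	adult_body	2	Facial plate, median carina
16	adult_body	2	Compound eye, posterior margin
17	adult_body	2	Parafacial, setosity
18	adult_body	2	Parafacial setae, configuration
19	adult_body	2	Frontal setae, orientation of dorsal-most pair
20	adult_body	2	Mouthparts, development
21	adult_body	3	Palpus
22	adult_body	2	Occiput, setae
23	adult_body	5	Postpronotal setae, number
24	adult_body	2	Postpronotal setae, if three or more, position
25	adult_body	3	First postsutural supra-alar seta, size
26	adult_body	3	Subscutellum, development
27	adult_body	2	Subscutellum, sclerotisation
28	adult_body	2	Scutellum, apical setae
29	adult_body	2	Katepimeron, setae
30	adult_body	3	Metathoracic spiracular lappets
31	adult_body	2	Male fore tarsus
32	adult_body	2	Female fore tarsus
33	adult_body	2	Shape of tibiae of mid and hind legs
34	adult_body	2	Leg chaetotaxy
35	adult_body	2	Hind coxa, posterodorsal margin
36	adult_body	2	Lower calypter, shape
37	adult_body	2	Long trichia along margin of lower calypter
38	adult_body	3	Female wing, development
39	adult_body	2	Costa, indentation at level of R_4+5_
40	adult_body	2	Male wing pattern, three distinct whitish spots
41	adult_body	2	Female wing pattern, posterodistal whitish spot
42	adult_body	3	Vein R_1_, dorsal setae
43	adult_body	2	Vein R_4+5_, dorsal setae
44	adult_body	2	Vein R_4+5_, extent of dorsal setae, when present
45	adult_body	2	Bend of vein M_1_
46	adult_body	2	Vein M_1_, position of bend
47	adult_body	2	Vein M_1_, extent of distal part
48	adult_body	2	Vein M_1_, apical termination
49	adult_body	2	Crossvein dm-m, inclination
50	adult_body	2	CuA+CuP
51	adult_body	2	Tergite 3, median marginal setae
52	adult_body	2	Tergite 4, marginal setae
53	male_terminalia	2	Sternite 5, posteromedian notch
54	male_terminalia	2	Sternite 5, shape of transversal section
55	male_terminalia	2	Sternite 5, median tooth-like apophysis on lateral lobe
56	male_terminalia	2	Tergite 6, median marginal setae
57	male_terminalia	4	Tergite 6, shape
58	male_terminalia	2	Connection between tergite 6 and syntergosternite 7+8
59	male_terminalia	2	Connection between sternite 6 and syntergosternite 7+8 on right side
60	male_terminalia	2	Cerci, shape
61	male_terminalia	2	Cerci, medial connection
62	male_terminalia	2	Surstylus, shape
63	male_terminalia	2	Surstylus, bifid inner median extension
64	male_terminalia	2	Surstylus, setae on median extension
65	male_terminalia	2	Bacilliform sclerite and laterobasal margin of surstylus, connection
66	male_terminalia	2	Surstylus and epandrium, connection
67	male_terminalia	2	Hypandrial arms, shape
68	male_terminalia	2	Phallic guide and pregonites, connection
69	male_terminalia	2	Postgonite, anterior seta
70	male_terminalia	2	Extension(s) of dorsal sclerite of distiphallus
71	male_terminalia	2	Extension(s) of dorsal sclerite of distiphallus, longitudinal division
72	male_terminalia	2	Extension(s) of dorsal sclerite of distiphallus, sclerotised connection with dorsal sclerite of distiphallus
73	male_terminalia	2	Membranous flag distal to extension of dorsal sclerite of distiphallus
74	male_terminalia	2	Median process of ventral sclerotisation of distiphallus
75	male_terminalia	2	Median process of ventral sclerotisation of distiphallus, connection with ventral plate
76	male_terminalia	2	Median process of ventral sclerotisation of distiphallus, longitudinal division
77	male_terminalia	2	Median process of ventral sclerotisation of distiphallus, length
78	male_terminalia	2	Median process of ventral sclerite of distiphallus, asymmetry
79	male_terminalia	2	Acrophallus, shape
80	male_terminalia	2	Semi-cylindrical dorsal sclerite of acrophallus
81	male_terminalia	2	Distiphallus, helmet-shaped, partly sclerotised envelope
82	female_terminalia	2	Ovipositor
83	larva	2	Labrum
84	larva	3	Locomotory behaviour
85	larva	2	Antenna
86	larva	2	Posterior part of anal division modified as a terminal sucker
87	larva	2	Mandibles
88	larva	2	Shape of mandible
89	larva	2	Labrum, connection with cephaloskeleton
90	larva	2	Body shape
91	larva	2	Parastomal bar of cephaloskeleton
92	larva	2	Longitudinal incision on parastomal bar of cephaloskeleton
93	larva	2	Fleshy protuberances (= prolegs) on segments
94	larva	2	Shape of ventral part of pseudocephalon
95	larva	2	Longitudinal cuticular ridges posteroventrally on anal division
96	larva	2	Tongue-like projection posterodorsally on anal division
97	larva	2	Pair of more or less elongated or globular vesicles posteroventrally on anal division
98	larva	2	Shape of posteroventral vesicles, is present
99	larva	2	Mandible, number of teeth (if present)
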