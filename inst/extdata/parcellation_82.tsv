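index	name	hemisphere	lobe	tissue_class
0	lh.bankssts	lh	T	cortical
1	lh.caudalanteriorcingulate	lh	F	cortical
2	lh.caudalmiddlefrontal	lh	F	cortical
3	lh.cuneus	lh	O	cortical
4	lh.entorhinal	lh	T	cortical
5	lh.frontalpole	lh	F	cortical
6	lh.fusiform	lh	T	cortical
7	lh.inferiorparietal	lh	P	cortical
8	lh.inferiortemporal	lh	T	cortical
9	lh.insula	lh	insula	cortical
10	lh.isthmuscingulate	lh	P	cortical
11	lh.lateraloccipital	lh	O	cortical
12	lh.lateralorbitofrontal	lh	F	cortical
13	lh.lingual	lh	O	cortical
14	lh.medialorbitofrontal	lh	F	cortical
15	lh.middletemporal	lh	T	cortical
16	lh.paracentral	lh	F	cortical
17	lh.parahippocampal	lh	T	cortical
18	lh.parsopercularis	lh	F	cortical
19	lh.parsorbitalis	lh	F	cortical
20	lh.parstriangularis	lh	F	cortical
21	lh.pericalcarine	lh	O	cortical
22	lh.postcentral	lh	P	cortical
23	lh.posteriorcingulate	lh	P	cortical
24	lh.precentral	lh	F	cortical
25	lh.precuneus	lh	P	cortical
26	lh.rostralanteriorcingulate	lh	F	cortical
27	lh.rostralmiddlefrontal	lh	F	cortical
28	lh.superiorfrontal	lh	F	cortical
29	lh.superiorparietal	lh	P	cortical
30	lh.superiortemporal	lh	T	cortical
31	lh.supramarginal	lh	P	cortical
32	lh.temporalpole	lh	T	cortical
33	lh.transversetemporal	lh	T	cortical
34	lh.accumbens	lh	subcortical	subcortical
35	lh.amygdala	lh	subcortical	subcortical
36	lh.caudate	lh	subcortical	subcortical
37	lh.hippocampus	lh	subcortical	subcortical
38	lh.pallidum	lh	subcortical	subcortical
39	lh.putamen	lh	subcortical	subcortical
40	lh.thalamus	lh	subcortical	subcortical
41	rh.bankssts	rh	T	cortical
42	rh.caudalanteriorcingulate	rh	F	cortical
43	rh.caudalmiddlefrontal	rh	F	cortical
44	rh.cuneus	rh	O	cortical
45	rh.entorhinal	rh	T	cortical
46	rh.frontalpole	rh	F	cortical
47	rh.fusiform	rh	T	cortical
48	rh.inferiorparietal	rh	P	cortical
49	rh.inferiortemporal	rh	T	cortical
50	rh.insula	rh	insula	cortical
51	rh.isthmuscingulate	rh	P	cortical
52	rh.lateraloccipital	rh	O	cortical
53	rh.lateralorbitofrontal	rh	F	cortical
54	rh.lingual	rh	O	cortical
55	rh.medialorbitofrontal	rh	F	cortical
56	rh.middletemporal	rh	T	cortical
57	rh.paracentral	rh	F	cortical
58	rh.parahippocampal	rh	T	cortical
59	rh.parsopercularis	rh	F	cortical
60	rh.parsorbitalis	rh	F	cortical
61	rh.parstriangularis	rh	F	cortical
62	rh.pericalcarine	rh	O	cortical
63	rh.postcentral	rh	P	cortical
64	rh.posteriorcingulate	rh	P	cortical
65	rh.precentral	rh	F	cortical
66	rh.precuneus	rh	P	cortical
67	rh.rostralanteriorcingulate	rh	F	cortical
68	rh.rostralmiddlefrontal	rh	F	cortical
69	rh.superiorfrontal	rh	F	cortical
70	rh.superiorparietal	rh	P	cortical
71	rh.superiortemporal	rh	T	cortical
72	rh.supramarginal	rh	P	cortical
73	rh.temporalpole	rh	T	cortical
74	rh.transversetemporal	rh	T	cortical
75	rh.accumbens	rh	subcortical	subcortical
76	rh.amygdala	rh	subcortical	subcortical
77	rh.caudate	rh	subcortical	subcortical
78	rh.hippocampus	rh	subcortical	subcortical
79	rh.pallidum	rh	subcortical	subcortical
80	rh.putamen	rh	subcortical	subcortical
81	rh.thalamus	rh	subcortical	subcortical
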