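class	total	exp_within	pred_within	exp_below	pred_below	err_below	exp_above	pred_above	err_above
Mu	1706	981	979	355	349	6	370	335	35
Sigma	694	592	592	66	66	0	36	36	0
Alpha	1520	734	734	495	471	24	291	289	2
Pi	609	323	323	158	158	0	128	124	4
Theta	1428	560	560	545	540	5	323	323	0
Delta-Epsilon	822	715	715	68	68	0	39	39	0
Omega	1349	556	556	617	597	20	176	176	0
Zeta	728	268	268	122	122	0	338	338	0
DHAR	10	0	0	7	7	0	3	3	0
Tau	1342	851	851	222	219	3	269	268	1
Phi	1711	1066	1066	177	177	0	468	468	0
HSP26	433	363	363	48	48	0	22	22	0
LanC	450	177	177	109	109	0	164	164	0
Kappa	1148	230	230	554	554	0	364	364	0
MAPEG	1111	687	687	143	143	0	281	281	0
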