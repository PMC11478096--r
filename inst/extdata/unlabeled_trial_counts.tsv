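region	bacteria	amoebozoa	fungi	viridiplantae	platyhelminthes	nematoda	arthropoda	mollusca	actinopterygii	amphibia	aves	mammalia	others
within	16475	16	2178	2729	10	510	2206	124	370	15	125	247	1175
below	11288	6	626	1493	66	237	443	52	426	39	159	509	677
above	12917	22	3743	2260	18	119	388	45	342	15	56	148	1007
total	41075	44	6582	6851	99	883	3063	222	1157	69	345	928	2889
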