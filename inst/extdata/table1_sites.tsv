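island	archipelago	island_type	area_km2	distance_km	unep_index	slmp	gmmc	elevation_max_m
Canary Islands	Canary Islands	oceanic	7509.66	116.63	30.4	0.812	0	3705
Cape Verde	Cape Verde Islands	oceanic	4088.52	586.53	55	0.466	0	2813
Bijagós	Bijagós Islands	continental	1944.72	0.83	10.8	1.123	1	59
Bioko	Cameroon Line	continental	1950.46	73.03	17	1.148	1	3011
Annobón	Cameroon Line	oceanic	15.7	350	45	–	0	587
São Tomé	Cameroon Line	oceanic	854.8	283.63	39	0.753	0	1977
Príncipe	Cameroon Line	oceanic	143.16	221.72	39	0.86	0	934
Bugala	Lake Victoria	lacustrine	296	3.7	5.487	–	1	160
Koome	Lake Victoria	lacustrine	100	14.3	10.688	–	1	180
Mfangano	Lake Victoria	lacustrine	66	7.4	10.414	–	1	551
Ukara	Lake Victoria	lacustrine	80	22.8	15.623	–	1	162
Pemba	Zanzibar	continental	987.08	68.6	31.231	1.178	0	149
Zanzibar	Zanzibar	continental	1591.5	50.9	17	1.337	1	133
Mafia	Mafia	continental	443.24	36.06	29.432	1.194	1	66
Grande Comore	Comoros	oceanic	1021.61	307.45	49	0.736	0	2368
Moheli	Comoros	oceanic	212.09	340.61	49	0.754	0	793
Anjouan	Comoros	oceanic	432.08	417.78	49	0.706	0	1591
Mayotte	Comoros	oceanic	371.42	490.16	47	0.669	0	636
Madagascar	Madagascar	oceanic	590547.4	780.51	58	0.46	0	2876
Ile Europa	French Territory	oceanic	32.64	492.95	67.941	0.736	0	20
Réunion	Mascarene Islands	oceanic	2512.65	1699.32	73	0.467	0	3066
Mauritius	Mascarene Islands	oceanic	1868.44	1874.49	87	0.399	0	816
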