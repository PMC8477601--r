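site	species	sporozoite_rate	vector_status
São Tomé	Anopheles coluzzii	0.03	primary
São Tomé	Anopheles coustani	0.002	secondary
Príncipe	Anopheles coluzzii	0.03	primary
Grande Comore	Anopheles gambiae	0.04	primary
Grande Comore	Anopheles funestus	0.02	primary
Grande Comore	Anopheles maculipalpis	–	other
Bioko	Anopheles gambiae	0.04	primary
Bioko	Anopheles coluzzii	0.03	primary
Bioko	Anopheles funestus	0.02	primary
Bioko	Anopheles moucheti	0.008	secondary
Bioko	Anopheles nili	0.015	primary
Bioko	Anopheles paludis	0.005	secondary
Bioko	Anopheles hancocki	0.003	secondary
Bioko	Anopheles coustani	–	other
Bugala	Anopheles gambiae	0.04	primary
Bugala	Anopheles funestus	0.02	primary
Bugala	Anopheles rivulorum	0.004	secondary
Mauritius	Anopheles arabiensis	0.012	primary
Mauritius	Anopheles coustani	–	other
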