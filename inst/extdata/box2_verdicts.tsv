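site	target_present	geographic_isolation	genetic_isolation	genetic_diversity	size	topography	richness	insecticide	plasmodium	endangered	travel
Canary Islands	fail	pass	missing	missing	pass	pass	pass	deferred	fail	deferred	pass
Cape Verde	fail	pass	missing	missing	pass	pass	pass	deferred	fail	deferred	pass
Annobón	pass	pass	pass	missing	fail	pass	pass	deferred	pass	deferred	fail
São Tomé	pass	pass	pass	pass	pass	pass	pass	deferred	pass	deferred	pass
Príncipe	pass	pass	pass	pass	pass	pass	pass	deferred	pass	deferred	pass
Grande Comore	pass	pass	pass	pass	pass	pass	pass	deferred	pass	deferred	pass
Moheli	pass	pass	pass	pass	pass	pass	pass	deferred	pass	deferred	pass
Anjouan	pass	pass	pass	pass	pass	pass	pass	deferred	pass	deferred	pass
Mayotte	pass	pass	pass	pass	pass	pass	pass	deferred	pass	deferred	pass
Ile Europa	missing	pass	missing	missing	fail	fail	pass	deferred	missing	deferred	fail
Madagascar	pass	pass	pass	pass	fail	pass	fail	deferred	pass	deferred	pass
Mauritius	fail	pass	missing	missing	pass	pass	pass	deferred	fail	deferred	pass
Réunion	fail	pass	missing	missing	pass	pass	pass	deferred	fail	deferred	pass
Bijagós	pass	fail	pass	fail	pass	fail	fail	deferred	pass	deferred	pass
Bioko	pass	pass	pass	missing	pass	pass	fail	deferred	pass	deferred	pass
Zanzibar	pass	fail	missing	missing	pass	fail	fail	deferred	pass	deferred	pass
Pemba	pass	fail	missing	missing	pass	fail	pass	deferred	pass	deferred	pass
Mafia	pass	fail	missing	missing	pass	fail	missing	deferred	pass	deferred	pass
Bugala	pass	fail	fail	fail	pass	fail	pass	deferred	pass	deferred	pass
Koome	pass	fail	fail	fail	pass	fail	pass	deferred	pass	deferred	pass
Mfangano	pass	fail	fail	fail	pass	fail	pass	deferred	pass	deferred	pass
Ukara	pass	fail	fail	fail	pass	fail	pass	deferred	pass	deferred	pass
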