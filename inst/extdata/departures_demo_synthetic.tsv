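origin	destination_region	mode	count
São Tomé	Central Africa	air	820
São Tomé	West Africa	air	310
São Tomé	Europe	air	260
São Tomé	Central Africa	sea	95
São Tomé	Europe	sea	22
Comoros	East Africa	air	640
Comoros	Middle East	air	210
Comoros	Indian Ocean	sea	180
Cape Verde	West Africa	air	2400
Cape Verde	Europe	air	3900
Cape Verde	South America	sea	2100
Cape Verde	Europe	sea	2600
Cape Verde	West Africa	sea	1400
Uganda	East Africa	air	10400
Uganda	Europe	air	4200
Uganda	Middle East	air	3100
Tanzania	East Africa	air	12800
Tanzania	Indian Ocean	sea	5400
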