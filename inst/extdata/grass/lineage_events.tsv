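lineage	kind	count
rice	transposition	177
brachypodium	ccf	7
brachypodium	inversion	6
brachypodium	transposition	82
sorghum	ccf	2
sorghum	inversion	5
sorghum	transposition	135
maize	ccf	7
maize	tcf	10
maize	inversion	34
maize	transposition	1673
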