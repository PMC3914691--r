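species	retained_duplicates
rice	129
brachypodium	106
sorghum	59
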