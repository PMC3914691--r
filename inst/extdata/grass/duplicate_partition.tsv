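genome	dated_pairs	retained
rice	604	427
brachypodium	475	355
sorghum	410	245
maize	647	247
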