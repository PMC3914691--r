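compartment	annotated	retained
A1	17937	7466
A5	10411	3478
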