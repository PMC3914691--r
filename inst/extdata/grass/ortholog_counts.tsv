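pair	genome	n_a	n_b
A1_A5	maize	740	309
A11_A12	rice	168	130
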