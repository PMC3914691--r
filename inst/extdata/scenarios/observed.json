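{
  "description": "Observed dominance (D/S) and segment labels of the n = 12 post-WGD ancestral intermediate, as read from the four modern grass genomes; A2 and A3 are composite fusion products.",
  "chromosomes": [
    {"name": "A1", "dom": "D", "segments": ["D"]},
    {"name": "A2", "dom": "D", "segments": ["S", "D"]},
    {"name": "A3", "dom": "D", "segments": ["D", "D"]},
    {"name": "A4", "dom": "D", "segments": ["D"]},
    {"name": "A5", "dom": "S", "segments": ["S"]},
    {"name": "A6", "dom": "S", "segments": ["S"]},
    {"name": "A7", "dom": "S", "segments": ["S"]},
    {"name": "A8", "dom": "S", "segments": ["S"]},
    {"name": "A9", "dom": "D", "segments": ["D"]},
    {"name": "A10", "dom": "S", "segments": ["S"]},
    {"name": "A11", "dom": "D", "segments": ["D"]},
    {"name": "A12", "dom": "S", "segments": ["S"]}
  ]
}
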