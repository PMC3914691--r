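{
  "id": "scenario2",
  "n": 5,
  "description": "Alternative n = 5 ancestor composed of the dominant protochromosomes (A1, A3, A4, A9, A11); A7/A10 and A6/A2 derive from fissions of the sensitive WGD copies A3p and A4p. Dominance is consistent but the fission products carry nonfunctional centromeres.",
  "ancestor": [
    {"name": "A1", "dom": "D"},
    {"name": "A3", "dom": "D"},
    {"name": "A4", "dom": "D"},
    {"name": "A9", "dom": "D"},
    {"name": "A11", "dom": "D"}
  ],
  "events": [
    {"kind": "wgd", "copies": [
      {"parent": "A1", "copy": "A5", "copy_dom": "S"},
      {"parent": "A3", "copy": "A3p", "copy_dom": "S"},
      {"parent": "A4", "copy": "A4p", "copy_dom": "S"},
      {"parent": "A9", "copy": "A8", "copy_dom": "S"},
      {"parent": "A11", "copy": "A12", "copy_dom": "S"}
    ]},
    {"kind": "fission", "chrom": "A3p", "products": ["A7", "A10"]},
    {"kind": "fission", "chrom": "A4p", "products": ["A6", "A2"]}
  ]
}
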