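{
  "id": "scenario5",
  "n": 6,
  "description": "n = 6 hybrid: A2 arises by centromeric fusion of A4p (S) and A6p (D) (as in the n = 7 scenario) but A3-A7-A10 derive from a fission of the sensitive WGD copy of a single A3 ancestor. The fission products carry nonfunctional centromeres and the composite structure of A3 is not reproduced.",
  "ancestor": [
    {"name": "A1", "dom": "D"},
    {"name": "A9", "dom": "D"},
    {"name": "A11", "dom": "D"},
    {"name": "A4", "dom": "D"},
    {"name": "A6p", "dom": "D"},
    {"name": "A3", "dom": "D"}
  ],
  "events": [
    {"kind": "wgd", "copies": [
      {"parent": "A1", "copy": "A5", "copy_dom": "S"},
      {"parent": "A9", "copy": "A8", "copy_dom": "S"},
      {"parent": "A11", "copy": "A12", "copy_dom": "S"},
      {"parent": "A4", "copy": "A4p", "copy_dom": "S"},
      {"parent": "A6p", "copy": "A6", "copy_dom": "S"},
      {"parent": "A3", "copy": "A3p", "copy_dom": "S"}
    ]},
    {"kind": "ccf", "chroms": ["A4p", "A6p"], "product": "A2", "declared_dom": "D"},
    {"kind": "fission", "chrom": "A3p", "products": ["A7", "A10"]}
  ]
}
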