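{
  "id": "scenario1",
  "n": 5,
  "description": "Historical n = 5 ancestor (A4, A5, A7, A8, A11) in which the sensitive A5, A8 are proposed to duplicate into chromosomes observed as dominant (A1, A9), and A3 arises from the fusion of two sensitive fission arms (A7L + A10S declared dominant). Violates the no-S-to-D rule and centromere functionality.",
  "ancestor": [
    {"name": "A4", "dom": "D"},
    {"name": "A5", "dom": "S"},
    {"name": "A7", "dom": "S"},
    {"name": "A8", "dom": "S"},
    {"name": "A11", "dom": "D"}
  ],
  "events": [
    {"kind": "wgd", "copies": [
      {"parent": "A4", "copy": "A6", "copy_dom": "S"},
      {"parent": "A5", "copy": "A1", "copy_dom": "D"},
      {"parent": "A7", "copy": "A10", "copy_dom": "S"},
      {"parent": "A8", "copy": "A9", "copy_dom": "D"},
      {"parent": "A11", "copy": "A12", "copy_dom": "S"}
    ]},
    {"kind": "fission", "chrom": "A7", "products": ["A7", "A7L"]},
    {"kind": "fission", "chrom": "A10", "products": ["A10", "A10S"]},
    {"kind": "tcf", "chroms": ["A7L", "A10S"], "product": "A3", "declared_dom": "D"},
    {"kind": "fission", "chrom": "A4", "products": ["A4", "A4L"]},
    {"kind": "fission", "chrom": "A6", "products": ["A6", "A6S"]},
    {"kind": "ccf", "chroms": ["A4L", "A6S"], "product": "A2", "declared_dom": "D"},
    {"kind": "fission", "chrom": "A12", "products": ["A12", "A12t"]},
    {"kind": "ccf", "chroms": ["A3", "A12t"], "product": "A3"}
  ]
}
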