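{
  "id": "scenario4",
  "n": 6,
  "description": "n = 6 hybrid: A3 arises by telomeric fusion of the dominant A7p and A10p (as in the n = 7 scenario) but the A2-A4-A6 group derives from a fission of the sensitive A4p copy. The fission products carry nonfunctional centromeres and A2 descends from a sensitive copy while observed dominant.",
  "ancestor": [
    {"name": "A1", "dom": "D"},
    {"name": "A9", "dom": "D"},
    {"name": "A11", "dom": "D"},
    {"name": "A4", "dom": "D"},
    {"name": "A7p", "dom": "D"},
    {"name": "A10p", "dom": "D"}
  ],
  "events": [
    {"kind": "wgd", "copies": [
      {"parent": "A1", "copy": "A5", "copy_dom": "S"},
      {"parent": "A9", "copy": "A8", "copy_dom": "S"},
      {"parent": "A11", "copy": "A12", "copy_dom": "S"},
      {"parent": "A4", "copy": "A4p", "copy_dom": "S"},
      {"parent": "A7p", "copy": "A7", "copy_dom": "S"},
      {"parent": "A10p", "copy": "A10", "copy_dom": "S"}
    ]},
    {"kind": "tcf", "chroms": ["A10p", "A7p"], "product": "A3", "declared_dom": "D"},
    {"kind": "fission", "chrom": "A4p", "products": ["A6", "A2"]}
  ]
}
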