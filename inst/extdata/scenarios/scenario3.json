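{
  "id": "scenario3",
  "n": 7,
  "description": "n = 7 ancestor, all protochromosomes dominant. After WGD the sensitive sisters are A5, A8, A12, A4p, A6, A7, A10. A2 arises by centromeric fusion of A4p (S) and the ancestral A6p (D), i.e. S + D = D; A3 by telomeric fusion of the A10p-derived arm with A7p (D + D = D) after a centromeric fission of A10p whose small acentric remnant is lost. Interpretive placement of the single fission (the observable labels do not determine a chromosome for it).",
  "ancestor": [
    {"name": "A1", "dom": "D"},
    {"name": "A9", "dom": "D"},
    {"name": "A11", "dom": "D"},
    {"name": "A4", "dom": "D"},
    {"name": "A6p", "dom": "D"},
    {"name": "A7p", "dom": "D"},
    {"name": "A10p", "dom": "D"}
  ],
  "events": [
    {"kind": "wgd", "copies": [
      {"parent": "A1", "copy": "A5", "copy_dom": "S"},
      {"parent": "A9", "copy": "A8", "copy_dom": "S"},
      {"parent": "A11", "copy": "A12", "copy_dom": "S"},
      {"parent": "A4", "copy": "A4p", "copy_dom": "S"},
      {"parent": "A6p", "copy": "A6", "copy_dom": "S"},
      {"parent": "A7p", "copy": "A7", "copy_dom": "S"},
      {"parent": "A10p", "copy": "A10", "copy_dom": "S"}
    ]},
    {"kind": "fission", "chrom": "A10p", "products": ["A10pMain", "A10pFrag"]},
    {"kind": "deletion", "chrom": "A10pFrag"},
    {"kind": "tcf", "chroms": ["A10pMain", "A7p"], "product": "A3", "declared_dom": "D"},
    {"kind": "ccf", "chroms": ["A4p", "A6p"], "product": "A2", "declared_dom": "D"}
  ]
}
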