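{
  "name": "cusativin (band midpoints)",
  "p": {
    "ApU": 0.22,
    "CpA": 0.8,
    "CpG": 0.9,
    "CpU": 0.9,
    "UpA": 0.8,
    "UpU": 0.22
  },
  "overrides": {
    "Cp[m22G]": 0.55,
    "[m5C]pU": 0.99
  },
  "product_terminus3": "cyclic_phosphate"
}
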