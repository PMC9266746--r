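{
  "name": "RNase MC1 (band midpoints)",
  "p": {
    "ApA": 0.025,
    "ApC": 0.025,
    "ApU": 0.85,
    "CpA": 0.15,
    "CpG": 0.005,
    "CpU": 0.9,
    "GpU": 0.0125,
    "UpA": 0.025,
    "UpU": 0.525
  },
  "overrides": {
    "[D]p[D]": 0.66,
    "[m5C]pU": 0.995,
    "Gp[D]": 0,
    "[m7G]pU": 0,
    "[m1A]pU": 0
  },
  "product_terminus3": "cyclic_phosphate"
}
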