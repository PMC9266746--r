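{
  "name": "RNase T1",
  "p": {
    "GpA": 1,
    "GpC": 1,
    "GpG": 1,
    "GpU": 1
  },
  "product_terminus3": "cyclic_phosphate"
}
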