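{
  "version": 1,
  "unit": "Da",
  "elements": {
    "C": 12,
    "H": 1.00782503207,
    "N": 14.0030740048,
    "O": 15.9949146196
  },
  "electron": 0.00054857990946
}
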