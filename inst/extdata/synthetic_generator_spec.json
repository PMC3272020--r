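{
  "n": 12,
  "theta": 30,
  "means": [
    [0.4, 0.25, 0.2, 0.1, 0.05]
  ],
  "library_size": {
    "law": "fixed",
    "j": 100
  },
  "seed": 7
}
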