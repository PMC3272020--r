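{
  "positive": "healthy",
  "threshold": 0.5,
  "classes": ["dysbiotic", "healthy"],
  "matrix": [
    [12, 0],
    [0, 12]
  ],
  "error_rate": 0
}
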