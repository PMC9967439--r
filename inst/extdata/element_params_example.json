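{
  "H": {
    "electrons": 1,
    "shells": [
      {"c": 0.3183098861837907, "p": 0, "a": 2.0}
    ]
  }
}
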