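{
  "henle": [62.4, -38.1, 21.7],
  "zyg_a": [35.0, -12.6, 22.9],
  "zyg_b": [48.8, -21.4, 22.3]
}
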