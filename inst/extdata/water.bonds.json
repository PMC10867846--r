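{
  "bonds": [[1, 2, 1], [1, 3, 1]],
  "formal_charge": 0
}
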