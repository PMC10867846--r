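{
  "scheme": "element",
  "entries": [
    {"match": "C", "alpha_bohr3": 9.4},
    {"match": "H", "alpha_bohr3": 2.7},
    {"match": "O", "alpha_bohr3": 5.4},
    {"match": "N", "alpha_bohr3": 7.4}
  ]
}
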