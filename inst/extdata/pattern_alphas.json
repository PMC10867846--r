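{
  "scheme": "pattern",
  "entries": [
    {"match": "[#6]", "alpha_bohr3": 9.4},
    {"match": "[#1]", "alpha_bohr3": 2.7},
    {"match": "[#8]", "alpha_bohr3": 5.4},
    {"match": "[#7]", "alpha_bohr3": 7.4},
    {"match": "[#6X4]-[#8]", "alpha_bohr3": 8.8},
    {"match": "[#8H1]", "alpha_bohr3": 5.9}
  ]
}
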