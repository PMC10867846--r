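{
  "types": [
    {"name": "c4-c3", "smarts1": "[#6X4]", "smarts2": "[#6X3]", "order": 1, "bcc_e": 0.02},
    {"name": "c4-c4", "smarts1": "[#6X4]", "smarts2": "[#6X4]", "order": 1, "bcc_e": 0.0},
    {"name": "c-o",  "smarts1": "[#6]", "smarts2": "[#8]", "order": 1, "bcc_e": 0.08},
    {"name": "c=o",  "smarts1": "[#6]", "smarts2": "[#8]", "order": 2, "bcc_e": 0.15},
    {"name": "c-n",  "smarts1": "[#6]", "smarts2": "[#7]", "order": 1, "bcc_e": 0.06},
    {"name": "ar-cc", "smarts1": "[c]", "smarts2": "[c]", "order": "ar", "bcc_e": 0.0},
    {"name": "ar-ch", "smarts1": "[c]", "smarts2": "[#1]", "order": 1, "bcc_e": -0.01},
    {"name": "c-h",  "smarts1": "[#6]", "smarts2": "[#1]", "order": 1, "bcc_e": -0.03},
    {"name": "o-h",  "smarts1": "[#8]", "smarts2": "[#1]", "order": 1, "bcc_e": 0.20},
    {"name": "n-h",  "smarts1": "[#7]", "smarts2": "[#1]", "order": 1, "bcc_e": 0.12}
  ]
}
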