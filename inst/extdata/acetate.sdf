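acetate
  dpolkit

  7  6  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0
    1.5200    0.0000    0.0000 C   0  0
    2.1500    1.0911    0.0000 O   0  0
    2.1500   -1.0911    0.0000 O   0  0
   -0.3633    0.9360    0.4230 H   0  0
   -0.3633   -0.8344    0.5992 H   0  0
   -0.3633   -0.1016   -1.0222 H   0  0
  1  2  1  0
  2  3  2  0
  2  4  1  0
  1  5  1  0
  1  6  1  0
  1  7  1  0
M  CHG  1   4  -1
M  END
$$$$
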