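methanol
  dpolkit

  6  5  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0
    1.4300    0.0000    0.0000 O   0  0
   -0.3633    0.9360    0.4230 H   0  0
   -0.3633   -0.8344    0.5992 H   0  0
   -0.3633   -0.1016   -1.0222 H   0  0
    1.7343    0.9101    0.0000 H   0  0
  1  2  1  0
  1  3  1  0
  1  4  1  0
  1  5  1  0
  2  6  1  0
M  END
$$$$
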