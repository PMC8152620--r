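ethanol
  nmrdp4 hand-built example structure

  9  8  0  0  0  0  0  0  0  0999 V2000
   -0.8660    0.2500    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.2500    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    0.2500    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5000   -0.2500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.2500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3660    0.7500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -1.2500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5000   -0.7500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5000   -0.2500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  1  4  1  0
  1  5  1  0
  1  6  1  0
  2  7  1  0
  2  8  1  0
  3  9  1  0
M  END
$$$$
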