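genotype: WT
rates:
  delta: 6.14
  gamma: 7.76
  beta2: 27.25
  alpha2: 1.49
  d2: 1.17
  r2: 0.87
  d2p: 0.12
  r2p: 0.09
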