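genotype: E153A
rates:
  delta: 5.6
  gamma: 6.16
  beta2: 14.14
  alpha2: 1.51
  d2: 2.05
  r2: 0.86
  d2p: 0.3
  r2p: 0.06
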