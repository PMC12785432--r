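genotype: E153K
rates:
  delta: 5.34
  gamma: 5.17
  beta2: 17.27
  alpha2: 1.41
  d2: 1.09
  r2: 0.99
  d2p: 0.07
  r2p: 0.1
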