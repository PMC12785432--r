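genotype: WT
rates:
  k_on: 10.0
  k_off: 0.9
  delta: 5.0
  gamma: 4.0
  beta: 25.0
  alpha: 1.2
  d2: 20.0
  r2: 0.15
  d2p: 1.0
  r2p: 0.005
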