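states:
- A2R
- A2F
- A2O
- A2D
- A2Dp
open_states:
- A2O
edges:
- from: A2R
  to: A2F
  rate: delta
  conc_dep: no
  factor: 1.0
- from: A2F
  to: A2R
  rate: gamma
  conc_dep: no
  factor: 1.0
- from: A2F
  to: A2O
  rate: beta2
  conc_dep: no
  factor: 1.0
- from: A2O
  to: A2F
  rate: alpha2
  conc_dep: no
  factor: 1.0
- from: A2F
  to: A2D
  rate: d2
  conc_dep: no
  factor: 1.0
- from: A2D
  to: A2F
  rate: r2
  conc_dep: no
  factor: 1.0
- from: A2F
  to: A2Dp
  rate: d2p
  conc_dep: no
  factor: 1.0
- from: A2Dp
  to: A2F
  rate: r2p
  conc_dep: no
  factor: 1.0
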