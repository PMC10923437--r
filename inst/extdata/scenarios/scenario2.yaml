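# Scenario 2: bidirectional generative model, strong instruments.
model: bmr
blocks:
  - {n_instruments: 1, beta: 1, label: strong}
  - {n_instruments: 5, beta: 2, label: strong}
  - {n_instruments: 10, beta: 2, label: strong}
  - {n_instruments: 20, beta: 2, label: strong}
gamma_pairs:
  - [-1.9, -0.5]
  - [-1.9, 0.5]
  - [-0.9, 0.9]
  - [0.9, -0.9]
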