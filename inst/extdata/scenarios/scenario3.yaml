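# Scenario 3: bidirectional generative model, weak instruments.
model: bmr
blocks:
  - {n_instruments: 1, beta: 0.02, label: weak}
  - {n_instruments: 5, beta: 0.02, label: weak}
  - {n_instruments: 10, beta: 0.02, label: weak}
  - {n_instruments: 20, beta: 0.02, label: weak}
  - {n_instruments: 100, beta: 0.05, label: weak}
gamma_pairs:
  - [-1.9, -0.5]
  - [-1.9, 0.5]
  - [-0.9, 0.9]
  - [0.9, -0.9]
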