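# Scenario 1: unidirectional generative model, no reverse effect.
model: umr
blocks:
  - {n_instruments: 1, beta: 1, label: strong}
  - {n_instruments: 20, beta: 2, label: strong}
  - {n_instruments: 20, beta: 0.02, label: weak}
  - {n_instruments: 100, beta: 0.05, label: weak}
gamma_pairs:
  - [-1.9, 0]
  - [-0.9, 0]
  - [0.9, 0]
  - [1.9, 0]
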