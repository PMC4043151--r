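# Zero-edit configuration: synthetic analogue of the three-state,
# one-network-per-condition design. All analysis defaults (sigma = 1, k = 10,
# lambda0 = 0.001, 60/15/25 chronological split) are filled in automatically.
seed: 42
output_dir: results/run_default
inputs:
  - {subject: s1, state: REM, synthetic: REM, n_ipi: 3000}
  - {subject: s1, state: AWAKE, synthetic: AWAKE, n_ipi: 3000}
  - {subject: s1, state: SWS, synthetic: SWS, n_ipi: 3000}
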