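{
  "n_participants": 6,
  "seed": 7,
  "n_starts": 5,
  "alpha": 0.05,
  "max_missing": 0.5,
  "stimulus_effect": -1.5,
  "drug_phase_interaction": 0.5,
  "missingness_rate": 0.05,
  "out_dir": "results/demo"
}
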