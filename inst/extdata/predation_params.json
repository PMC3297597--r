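{
  "n_total": 200,
  "max_age": 5,
  "n_attacks": 20,
  "n_disturbances": 20,
  "beta": 0.1,
  "p_capture_f": 0.5,
  "p_capture_b": 0.8,
  "energy_gain": 8,
  "energy_cost_escape": 0.1,
  "repro_scale": 1,
  "repro_exponent": 1,
  "risk_mode": "frequency_dependent",
  "init_freq_f": 0.5,
  "init_age_distribution": "uniform",
  "max_seasons": 100000,
  "n_replicates": 1000,
  "base_seed": 1,
  "empty_group_renormalize": false
}
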