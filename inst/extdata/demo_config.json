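{
  "simulation": {
    "n_patients": 800,
    "n_genes": 400,
    "n_benefit_genes": 20,
    "mutation_freq_range": [0.15, 0.30],
    "arm_ratio": 0.5,
    "log_hr_treated_per_mutation": -0.2231435513,
    "log_hr_control_per_mutation": 0.0487901642,
    "log_hr_treatment_main": 0,
    "response_intercept": -6.2383246252,
    "response_score_by_arm_slope": 1.3862943611,
    "seed": 20260912
  },
  "selection": {
    "n_repetitions": 50,
    "top_k": 60,
    "label_spec": "responder",
    "mode": "frequency",
    "freq_threshold": 0.8,
    "stability_window": 25
  },
  "tmb_high_cutoff": 10,
  "cutpoint": {
    "endpoint": "pfs",
    "span": 0.8,
    "min_group_size": 20,
    "min_events": 5,
    "smooth": false
  },
  "evaluation": {
    "n_bootstrap": 500
  },
  "seed": 1
}
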