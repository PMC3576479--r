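{
  "label": "two-outcome-selection-strong-null",
  "null_structure": "strong",
  "generator": {
    "n_T": 5, "n_C": 5, "rho": 0.3, "seed": 1,
    "endpoints": [
      {"name": "sbp_change", "type": "continuous", "mean_T": 0, "mean_C": 0, "sd": 2},
      {"name": "dbp_change", "type": "continuous", "mean_T": 0, "mean_C": 0, "sd": 1}
    ]
  },
  "rule": {"name": "min_variance", "candidates": ["sbp_change", "dbp_change"]},
  "plan": {"endpoint": "sbp_change", "statistic": "diff_means", "alpha": 0.05},
  "reps": 2000,
  "seed": 7,
  "mode": "exact"
}
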