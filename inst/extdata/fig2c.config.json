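{
  "assembly": "fig1_4click.json",
  "backend": "ode",
  "ode": { "t_end": 4000, "n_samples": 2501 },
  "analysis": {
    "scan_grid": [0.02, 0.05, 0.08, 0.11, 0.14, 0.17, 0.2, 0.23],
    "stable_low_help": 0.05,
    "stable_high_help": 0.2,
    "transition_help": 0.146,
    "bistable_help": 0.2,
    "n_inits": 50,
    "return_map_lag": 1,
    "t_window": [200, 3600]
  },
  "seed": 11
}
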