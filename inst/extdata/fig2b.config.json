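{
  "assembly": "fig1_4click.json",
  "overrides": {
    "Tnk.initial_abundance": 0,
    "maturation_rate.Tc": 0.0055
  },
  "backend": "ode",
  "ode": { "t_end": 6000, "n_samples": 3001 },
  "seed": 0
}
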