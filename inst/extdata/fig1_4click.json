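{
  "_comment": "Calibrated default parameterization of the canonical 4-click. Rates are data: the resting state (bystander help 0.2) is a stable coexistence equilibrium (Tc 0.016, Tnk 0.027, Th 0.012, Tr1 0.856) approached from the shipped initial abundances with a Tr1 maximum near 0.87; reducing help below ~0.14, or depleting Tnk (fig2b preset), tips the system into the cytotoxic Tc-dominant state.",
  "populations": [
    { "id": "Tc",  "lineage": "cytotoxic", "stage": "young",
      "growth_rate": 1.2285, "death_rate": 0.0407, "help_coefficient": 0.0,
      "initial_abundance": 0.007 },
    { "id": "Tnk", "lineage": "cytotoxic", "stage": "mature",
      "growth_rate": 0.8652, "death_rate": 0.0784, "help_coefficient": 0.0,
      "initial_abundance": 0.016 },
    { "id": "Th",  "lineage": "helper", "stage": "young",
      "growth_rate": 1.1263, "death_rate": 0.0287, "help_coefficient": 1.0,
      "initial_abundance": 0.005 },
    { "id": "Tr1", "lineage": "helper", "stage": "mature",
      "growth_rate": 0.9846, "death_rate": 0.0850, "help_coefficient": 0.0,
      "initial_abundance": 0.3 }
  ],
  "kill_edges": [
    { "killer": "Tc",  "victim": "Tnk", "kill_rate": 0.7065,
      "mechanism": "recognition of trogocytosis-captured antigen" },
    { "killer": "Tnk", "victim": "Th",  "kill_rate": 2.7291,
      "mechanism": "NK receptor engagement of cognate ligand" },
    { "killer": "Th",  "victim": "Tr1", "kill_rate": 0.2041,
      "mechanism": "death-receptor engagement (Fas/FasL)" },
    { "killer": "Tr1", "victim": "Tc",  "kill_rate": 0.0541,
      "mechanism": "CTLA4-dependent transendocytosis" }
  ],
  "maturation_edges": [
    { "source": "Tc", "target": "Tnk", "rate": 0.0218 },
    { "source": "Th", "target": "Tr1", "rate": 0.0182 }
  ],
  "bystander_inputs": [
    { "target": "Th", "help_level": 0.2 }
  ],
  "carrying_capacity": 1
}
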