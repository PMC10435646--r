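# Demonstration run on a small synthetic cohort: two groups drawn from the
# same 86-region population (confound-free null), one planted hub in group
# A. Sized to finish in well under a minute.
synthetic:
  nPerGroup: {A: 15, B: 12}
  plantedHubs: {A: ["L Inferior temporal"]}
  seed: 42
max_density_rule: fixed
fixed_max_density: 0.44
ensemble_size: 10
n_perm: 100
seed: 42
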