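# Example study configuration: one scenario, reduced replicate counts.
# Keys mirror scenario_spec(); `seed` is mandatory (no wall-clock seeding).
seed: 42
n_individuals: 1000
maf: 0.4
h2: [0.001, 0.0, 0.0]
residual_corr: 0.7
n_replicates: 100
n_permutations: 10
alpha: 0.05
methods: [uv, cca, bayes, tates]
priors:
  v_b: 0.02
  iw_scale: 6
  iw_df: 4
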