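# Example end-to-end configuration for run_config_from_yaml().
seed: 1
tr: 2
learners_only: true
subsets: [all]
gen_instructed:
  n_subjects: 20
  noise_sd: 0.1
  model: {alpha: 0.061, rho: 0.943}
gen_uninstructed:
  n_subjects: 20
  noise_sd: 0.1
  model: {alpha: 0.042, variant: feedback}
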