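# Example cohort configuration for run_full() / the CLI full-run subcommand.
cohort_size: 20
seed: 1
sim:
  n_channels: 32
  n_trials: 192
preprocess:
  min_rt_ms: 700
  crop_ms: 500
cv:
  grid_size: 25
evaluation:
  bootstrap_iterations: 9999
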