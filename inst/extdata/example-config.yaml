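# Example experiment configuration for `run_pipeline()` / the progrisk CLI.
seed: 1
out_dir: progrisk_out
simulation:
  n_subjects: 400
  prog_fraction: 0.45
  payload: feature
preparation:
  horizons: [2]
  bmi_tolerance: 0.10
  age_tolerance: 0
training:
  formulations: [baseline, riskform2]
  margin: 2.0
  gamma: 1.0
  hyper:
    lr: 0.05
    epochs: 60
    batch_size: 64
evaluation:
  n_boot: 1000
  level: 0.95
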