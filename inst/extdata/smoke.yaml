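# Minimal end-to-end configuration: a tiny cohort and short training,
# meant to exercise every pipeline stage in seconds.
seed: 1
simulate:
  n_subjects: 8
  cycles_per_subject: 3
  group_split: 0.5
preprocess:
  cutoff: 20
  grf_threshold: 10
  n_points: 101
model:
  channels: 8
  kernel_size: 3
  dilations: [1, 2]
  dropout: 0.1
  static_units: 8
  head_units: [8]
  head_dropout: 0.1
train:
  epochs: 20
  batch_size: 8
  learning_rate: 0.001
evaluate:
  grouping: cycle
compare:
  enabled: true
  models: [hybrid, tcn_only, lstm]
  epochs: 20
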