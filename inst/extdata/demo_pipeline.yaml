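# Demonstration pipeline: synthesize plate competitions from a costly-
# cooperator truth, refit the competition model, and scan multilevel
# selection over structure strength. Runs in well under a minute.
seed: 42
stages: [synth, fit, scan]
inoculum: 1.0e+06
truth:
  q: 1.0
  Y_C: 0.8
  Y_D: 1.0
  N_min: 1.0e+06
  N_max: 4.0e+06
  g_sat: 12.0
  p_half: 0.25
  duration: 24
synth:
  levels: [0.01, 0.17, 0.5, 0.83, 0.99]
  replicates: 6
  noise_cv: 0.15
fit:
  n_starts: 12
scan:
  p_grid: {from: 0.05, to: 0.95, num: 19}
  sigma_grid: {from: 0.0, to: 5.0, num: 11}
  n_groups: 201
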