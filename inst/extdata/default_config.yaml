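geometry:
  lambda_g: 1.35
  L_A: 1.0
  A_ref: 15.0
diagram:
  v0: 1.012
  kappa: 0.017
  sigma_eps: 0.15
  v_min: 0.1
perception:
  data_fit:
    mu: 0.77
    sigma: 0.30
    beta: 0.68
  tuned:
    mu: 1.15
    sigma: 0.20
    beta: 0.33
  active: tuned
  deterministic_ratio: ~
sweep:
  n_min: 1
  n_max: 30
  realizations: 10000
  variants: [deterministic, velocity_noise, full]
dataset:
  n_frames: 50000
  count_law:
    type: uniform
    min: 1
    max: 25
  measurement_sd: 0.05
seed: 20221
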