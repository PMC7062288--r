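tissue:
  synthetic:
    width_mm: 8.0
    height_mm: 8.0
    tract:
      y_mm: 4.0
      thickness_mm: 1.0
    px_size: 25.0
    seed: 1.0
parameters:
  rho_R: 2.85073
  sigma_theta: 13.9376
  p0: 230.099
  D_p: 7.5e-05
  r_d: 0.399591
  r_s: 391.384
  r_c: 0.398009
  p_a: 47.3346
  K_p: 5.0
  K_m: 170.293
  beta_p: 0.654349
  beta_m: 0.122315
  tau_mean: 96.2931
  sigma_tau: 8.66468
  v_mean: 99.4477
  sigma_v: 28.3552
  kappa: 25.0
  dt: 0.5
  end_day: 17.0
  max_cells: 60000.0
snapshot_days:
- 5.0
- 10.0
- 17.0
seed: 1.0
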