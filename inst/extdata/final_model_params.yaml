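pk:
  cl_f_L_per_day: 504.0
  v1_f_L: 28.0
  q_f_L_per_day: 67.0
  v2_f_L: 40.0
  d1_day: 0.0625
  ref_weight_kg: 70.0
  exp_cl: 0.75
  exp_v: 1.0
pd:
  ke0_per_day: 0.0065
  e0_score: 48.51
  beta_age: -0.21
  deff_L_per_ug: 0.0022
  kprog_score_per_day: 0.015
  age_ref_years: 5.0
random_effects:
  omega_ke0: 0.21
  omega_e0: 0.2
  omega_deff: 1.4
  omega_kprog_score_per_day: 0.018
  corr_e0_kprog: 0.48
  sigma_add_score: 1.6
note: PK values are documented placeholders on an adult scale - substitute published
  adult estimates
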