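band_table:
  band:
  - 10-14 kg
  - 15-24 kg
  - 25-37 kg
  - 38-51 kg
  - '>=52 kg'
  lower:
  - 10.0
  - 15.0
  - 25.0
  - 38.0
  - 52.0
  upper:
  - 15.0
  - 25.0
  - 38.0
  - 52.0
  - .inf
  dose_g:
  - 2.0
  - 4.0
  - 7.0
  - 10.0
  - 14.0
arms:
- placebo
- low
- high
arm_ratio:
- 1.0
- 1.0
- 1.0
visit_days:
- 0.0
- 84.0
- 168.0
- 252.0
titration_days: 14.0
crossover_day: 84.0
treatment_end: 168.0
dose_interval: 0.5
dropout_prob: 0.0
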