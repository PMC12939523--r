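functional_unit:
  m_pc_per_cu: 7.12
  y_pc: 0.0322
  f_w: 0.158
  strength: 140.0
sequestration:
  r_soc: 25.0
  c_to_co2: 3.6666667
  reversal_buffer: 0.5
  uncertainty_margin: 0.3
  application_rate: 47.6
stages:
  cultivation_kg_per_cu: 0.15
  extraction_kg_per_cu: 4.83
  biofixation_kg_per_cu: 0.40179
  cultivation_kg_per_kg_wet: 4.19
  contributions:
    cultivation_energy: 5.15
    cultivation_yield: -5.6
    transport: 0.75
  sequestration_kg_per_cu: 1602.48
case_study:
  dosage_cu_per_kg: 0.28
  unit_mass_kg: 0.1
  overhead: 0.3
  colorant_share_kg: 0.0
  total_scope123_t: 2.637448e+07
  per_bag_delta_kg: 5.3488914
  cu_per_bag: 0.00056
  goals:
  - 0.05
  - 0.1
  - 0.2
  - 0.5
trial:
  baseline_stock_mean: 30.5
  between_core_cv: 0.12
  analytical_cv: 0.0344
  annual_effect_exp: 1.6
  annual_effect_ctrl: 0.0
  n_exp_t0: 9.0
  n_ctrl_t0: 6.0
  n_exp_t1: 9.0
  n_ctrl_t1: 9.0
  confidence: 0.9
  resamples: 10000.0
report:
  kg_digits: 2.0
  pct_digits: 1.0
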