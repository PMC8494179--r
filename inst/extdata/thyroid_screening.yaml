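schema_version: 1
settings:
  horizon_cycles: 55
  cycle_length: 1.0
  start_age: 20
  discount_rate: 0.05
  wtp_threshold: 50000.0
  psa_draws: 1000
  rng_seed: 1
  mtn_instant: yes
  exam_states: alive
  nf_states: btn
  tf_arms: SG
  ct_timing: entry
  exam_interval: 1
  discount_cycle_offset: 0.0
  half_cycle_correction: no
utilities:
  health: 1.0
  btn: 0.99
  mtn: 0.6
  postop: 0.99
  recurrence: 0.54
  death: 0.0
costs:
  c_t: 20174.578600000000733
  c_n: 251.460000000000008
  c_tf: 1264.90319999999997
  c_nf: 798.600000000000023
  c_recurrence: 6050.220000000000255
  c_o: 50.159999999999997
transitions:
  SG:
    p_health_btn: 0.19
    p_health_mtn: 3.9e-05
    p_btn_mtn: 0.00854478
    p_mtn_death: 3.0e-06
    p_postop_recurrence: 0.001029
  NSG:
    p_health_btn: 0.68
    p_health_mtn: 0.000583
    p_btn_mtn: 0.00854478
    p_mtn_death: 5.0e-06
    p_postop_recurrence: 0.001029
distributions:
  u_recurrence:
    family: beta
    shape_a: 176.0
    shape_b: 150.0
    base_value: 0.54
    range_low: 0.49
    range_high: 0.59
  u_postop:
    family: beta
    shape_a: 1.0
    shape_b: 0.0
    base_value: 0.99
    range_low: 0.74
    range_high: 1.0
  u_mtn:
    family: beta
    shape_a: 153.0
    shape_b: 102.0
    base_value: 0.6
    range_low: 0.54
    range_high: 0.66
  u_btn:
    family: beta
    shape_a: 100.0
    shape_b: 1.0
    base_value: 0.99
    range_low: 0.89
    range_high: 1.0
  c_t:
    family: gamma
    shape_a: 29.0
    shape_b: 706.0
    base_value: 20174.578600000000733
    range_low: 16737.470000000001164
    range_high: 24283.81000000000131
  c_n:
    family: gamma
    shape_a: 7.0
    shape_b: 34.0
    base_value: 251.460000000000008
    range_low: 126.060000000000002
    range_high: 311.519999999999982
  c_tf:
    family: gamma
    shape_a: 3.0
    shape_b: 492.0
    base_value: 1264.90319999999997
    range_low: 731.990000000000009
    range_high: 2309.309999999999945
  c_nf:
    family: gamma
    shape_a: 2.0
    shape_b: 449.0
    base_value: 798.600000000000023
    range_low: 399.300000000000011
    range_high: 1597.200000000000045
  c_recurrence:
    family: gamma
    shape_a: 4.0
    shape_b: 1513.0
    base_value: 6050.220000000000255
    range_low: 3024.7800000000002
    range_high: 9075.329999999999927
  c_o:
    family: gamma
    shape_a: 4.0
    shape_b: 13.0
    base_value: 50.159999999999997
    range_low: 25.079999999999998
    range_high: 75.239999999999995
  p_health_btn_sg:
    family: beta
    shape_a: 50.0
    shape_b: 211.0
    base_value: 0.19
    range_low: 0.14
    range_high: 0.24
  p_health_btn_nsg:
    family: beta
    shape_a: 19.0
    shape_b: 9.0
    base_value: 0.68
    range_low: 0.51
    range_high: 0.85
  p_health_mtn_sg:
    family: beta
    shape_a: 62.0
    shape_b: 1575948.0
    base_value: 3.9e-05
    range_low: 2.9e-05
    range_high: 4.9e-05
  p_health_mtn_nsg:
    family: beta
    shape_a: 61.0
    shape_b: 105337.0
    base_value: 0.000583
    range_low: 0.000437
    range_high: 0.000729
  p_btn_mtn:
    family: beta
    shape_a: 61.0
    shape_b: 7070.0
    base_value: 0.00854478
    range_low: 0.00640859
    range_high: 0.01068098
  p_mtn_death_sg:
    family: beta
    shape_a: 62.0
    shape_b: 23640522.0
    base_value: 3.0e-06
    range_low: 1.95e-06
    range_high: 3.25e-06
  p_mtn_death_nsg:
    family: beta
    shape_a: 62.0
    shape_b: 11175470.0
    base_value: 5.0e-06
    range_low: 4.0e-06
    range_high: 7.0e-06
  p_postop_recurrence:
    family: beta
    shape_a: 61.0
    shape_b: 59621.0
    base_value: 0.001029
    range_low: 0.000772
    range_high: 0.001286
life_table:
  kind: gompertz_makeham
  target_life_expectancy: 80.000000000000014
  max_age: 110
  makeham_a: 0.0006
  gompertz_theta: 0.095

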