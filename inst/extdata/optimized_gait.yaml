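spinal:
  K_l: 8.565639118063196
  K_v: 0.0
  h: 0.017852819989187
  c_ham: 0.008
  c_rf: 0.004644443816529
  g_sol: 0.000409310468269
  g_vas: 0.000328514529355
  g_gas: 0.0
  pko_margin: 0.251989341797622
  pko_kp: 7.138444987144281
  pko_kv: 0.0
  s0_sol: 0.001
  s0_ta: 0.066868603098604
  s0_gas: 0.001
  s0_vas: 0.001
  s0_ham: 0.001
  s0_rf: 0.001
  s0_glu: 0.096822213143393
  s0_hfl: 0.001
  s0_hab: 0.042211441467314
  s0_had: 0.040482848465652
  delay_ankle: 0.011333508922755
  delay_knee: 0.005
  delay_hip: 0.002
  stim_floor: 0.005561326591401
  tau_act: 0.008
  tau_deact: 0.034173529140949
c_lat: 0.0015
s_preswing: 0.3
balance:
  cd_early_sag: 0.635219511732535
  cv_early_sag: 0.6
  cd_late_sag: 0.784723835004225
  cv_late_sag: 0.0
  cd_early_fro: 0.0
  cv_early_fro: 0.26782299293404
  cd_late_fro: 0.635734915040544
  cv_late_fro: 0.04446796426935
control:
  theta_hipfl_early: 0.211418743362397
  theta_knee_early: 1.524729853493994
  theta_hipfl_late: 0.0
  theta_knee_late: 0.257668172548966
  theta_ankle: -0.042029559809564
  t_swing: 0.9
  theta_ref_hipfl: -0.1
  a_x: 1.709389468228009
  v_init: 1.447371371069763
fsm:
  early_share: 0.5
  min_stance: 0.2
  min_swing_frac: 0.5
  unload_frac: 0.25
  pushoff_timeout: 0.15
  t_first_step: 0.1
  flight_warn: 0.2
fall:
  height_frac: 0.7
  max_tilt: 1.0472
sim:
  dt: 0.0001
  control_dt: 0.001
  log_dt: 0.01
  udot_clamp: 30.0
  fl_fv_guard: 0.05
  plan_feedback: 0.02
  qdd_cap: 60.0
  tau_cap: 150.0
  plan_lookahead: 0.02
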