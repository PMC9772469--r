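# Default control parameters.
#
# spinal: the 27 spinal reflex parameters (flat vector, fixed across gaits):
#   K_l, K_v, h                      generic stretch reflex (shared, normalized
#                                    muscle-fiber length units l_ce/l_opt)
#   c_ham, c_rf                      force-modulated compliant hip gains (1/N)
#   g_sol, g_vas, g_gas              compliant-leg positive force feedback (1/N)
#   pko_margin, pko_kp, pko_kv       knee-overextension guard (rad, 1/rad, s/rad)
#   s0_*  (10)                       per-muscle tonic baseline stimulation
#   delay_ankle, delay_knee, delay_hip   pathway delays (s)
#   stim_floor                       stimulation floor
#   tau_act, tau_deact               activation time constants (s)
# balance: the 8 balance feedback gains of the swing hip target modulation
#   (position/velocity x early/late x sagittal/frontal).
# control: the 8 high-level control parameters + initial speed defining a gait.
spinal:
  K_l: 3.0
  K_v: 0.15
  h: 0.1
  c_ham: 4.0e-3
  c_rf: 2.5e-3
  g_sol: 2.5e-4
  g_vas: 2.5e-4
  g_gas: 1.0e-4
  pko_margin: 0.15
  pko_kp: 6.0
  pko_kv: 0.3
  s0_sol: 0.01
  s0_ta: 0.01
  s0_gas: 0.01
  s0_vas: 0.01
  s0_ham: 0.01
  s0_rf: 0.01
  s0_glu: 0.01
  s0_hfl: 0.01
  s0_hab: 0.05
  s0_had: 0.01
  delay_ankle: 0.020
  delay_knee: 0.010
  delay_hip: 0.005
  stim_floor: 0.001
  tau_act: 0.011
  tau_deact: 0.04

# fixed reflex-module constants (not gait control parameters):
# frontal-plane trunk reflex gain and the pre-swing push-off drive
c_lat: 1.5e-3
s_preswing: 0.30

balance:
  cd_early_sag: 0.6
  cv_early_sag: 0.25
  cd_late_sag: 0.1
  cv_late_sag: 0.05
  cd_early_fro: 0.6
  cv_early_fro: 0.3
  cd_late_fro: 0.3
  cv_late_fro: 0.15

control:
  theta_hipfl_early: 0.50   # rad, swing hip flexion target, end of early swing
  theta_knee_early: 1.00    # rad, swing knee flexion target, end of early swing
  theta_hipfl_late: 0.35    # rad, swing hip flexion target, end of late swing
  theta_knee_late: 0.25     # rad, swing knee flexion target, end of late swing
  theta_ankle: 0.15         # rad, swing ankle target (single segment)
  t_swing: 0.40             # s, total swing duration
  theta_ref_hipfl: 0.08     # rad, stance hip flexion reference (trunk lean)
  a_x: 0.30                 # m/s^2, constant forward propulsion acceleration
  v_init: 1.10              # m/s, initial forward speed (simulation onset only)

fsm:
  early_share: 0.5          # fraction of t_swing spent in early swing
  min_stance: 0.20          # s, minimum stance duration
  min_swing_frac: 0.5      # fraction of t_swing before touchdown can end swing
  unload_frac: 0.25         # push-off complete when own load < frac x body weight
  pushoff_timeout: 0.15     # s after contralateral touchdown
  t_first_step: 0.10        # s, scheduled first swing onset (left leg)
  flight_warn: 0.20         # s, both-feet-airborne anomaly threshold

fall:
  height_frac: 0.70         # fall when trunk CoM below this fraction of standing
  max_tilt: 1.0472          # rad (60 deg) trunk pitch/roll limit

sim:
  dt: 1.0e-4                # s, integrator step
  control_dt: 1.0e-3        # s, control tick (replanning, descending commands)
  log_dt: 0.01              # s, time-series logging interval
  udot_clamp: 30.0          # 1/s, clamp on descending-command rate
  fl_fv_guard: 0.05         # guard on f_l * f_v in the muscle inversion
  plan_feedback: 0.02       # per-tick pull of the plan toward the sensed state
  qdd_cap: 60.0             # rad/s^2, clamp on planned joint accelerations
  tau_cap: 150.0            # N m, clamp on commanded joint torques
  plan_lookahead: 0.02      # s, command lead over the plan (actuation latency)
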