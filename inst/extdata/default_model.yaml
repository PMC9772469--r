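# Default skeletal and muscular model: 1.80 m / 80 kg adult.
# Segment masses, lengths and inertias follow standard anthropometric
# proportion tables (Winter-style); the trunk segment lumps head, arms and
# trunk (HAT). Coordinates: forward = +x, left = +y, up = +z; angles rad.
# Sign conventions: positive joint torque = flexion (hip, knee),
# dorsiflexion (ankle), abduction (hip ab/adduction).
gravity: 9.81

contact:
  k: 80000.0        # N/m normal stiffness per sphere
  c: 1.0            # s/m velocity factor of the nonlinear spring-damper
  mu: 0.9           # Coulomb friction coefficient
  v_reg: 0.02       # m/s regularization speed for smooth stick-slip

trunk:
  mass: 54.24       # HAT: 0.678 x 80 kg
  com: [0.0, 0.0, 0.33]
  inertia: [4.9, 4.9, 1.5]
  hip_offset_y: 0.09

thigh:
  mass: 8.0
  length: 0.441
  com: [0.0, 0.0, -0.191]
  inertia: [0.162, 0.162, 0.030]

shank:
  mass: 3.72
  length: 0.443
  com: [0.0, 0.0, -0.192]
  inertia: [0.0666, 0.0666, 0.007]

foot:
  mass: 1.16
  com: [0.06, 0.0, -0.04]
  inertia: [0.002, 0.005, 0.005]
  ball_x: 0.16      # ball-of-foot hinge, x in foot (ankle) frame
  sole_z: -0.075    # sole level in foot frame
  spheres:          # left foot; right foot is mirrored in y
    - { pos: [-0.07, 0.03, -0.045], radius: 0.03 }
    - { pos: [-0.07, -0.03, -0.045], radius: 0.03 }
    - { pos: [0.16, 0.04, -0.045], radius: 0.03 }
    - { pos: [0.16, -0.04, -0.045], radius: 0.03 }

joints:
  damping: 0.3      # N m s/rad passive viscous damping, leg joints
  k_limit: 500.0    # N m/rad soft-stop stiffness at anatomical limits
  d_limit: 20.0     # N m s/rad soft-stop damping
  limits:           # rad, [min, max] per joint type
    hipab: [-0.35, 0.70]
    hipfl: [-0.60, 1.80]
    knee: [-0.03, 2.60]
    ankle: [-0.90, 0.90]

hill:
  fl_w: 0.56        # force-length width
  fl_c: -2.995732   # ln(0.05), force-length shape
  fv_K: 5.0         # force-velocity curvature
  fv_N: 1.5         # eccentric force enhancement
  see_eps_ref: 0.04 # tendon strain at F_max
  pe_w: 0.80        # parallel elastic width
  stim_floor: 0.001 # tonic stimulation floor

# Muscle routing: moment arm r0 signed by the torque convention above;
# "cos" arms vary as r0*cos(theta - th_max) (tendon-excursion consistent);
# th_ref is the joint angle at which the muscle sits at l_opt + l_slack.
# delay: proprioceptive loop delay by most distal spanned joint
# (ankle 20 ms, knee 10 ms, hip 5 ms).
muscles:
  - name: SOL
    fmax: 4000.0
    lopt: 0.04
    lslack: 0.26
    vmax_rel: 6.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.020
    arms:
      - { joint: ankle, type: cos, r0: -0.04, th_max: 0.0, th_ref: 0.05 }
  - name: TA
    fmax: 800.0
    lopt: 0.06
    lslack: 0.24
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.020
    arms:
      - { joint: ankle, type: cos, r0: 0.04, th_max: 0.0, th_ref: 0.05 }
  - name: GAS
    fmax: 1500.0
    lopt: 0.05
    lslack: 0.40
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.020
    arms:
      - { joint: ankle, type: cos, r0: -0.04, th_max: 0.0, th_ref: -0.05 }
      - { joint: knee, type: cos, r0: 0.03, th_max: 0.0, th_ref: 0.30 }
  - name: VAS
    fmax: 6000.0
    lopt: 0.08
    lslack: 0.23
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.010
    arms:
      - { joint: knee, type: cos, r0: -0.04, th_max: 0.3, th_ref: 0.35 }
  - name: HAM
    fmax: 3000.0
    lopt: 0.10
    lslack: 0.31
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.010
    arms:
      - { joint: hipfl, type: const, r0: -0.05, th_max: 0.0, th_ref: 0.25 }
      - { joint: knee, type: cos, r0: 0.035, th_max: 0.0, th_ref: 0.30 }
  - name: RF
    fmax: 1500.0
    lopt: 0.08
    lslack: 0.35
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.010
    arms:
      - { joint: hipfl, type: const, r0: 0.05, th_max: 0.0, th_ref: 0.25 }
      - { joint: knee, type: cos, r0: -0.03, th_max: 0.3, th_ref: 0.45 }
  - name: GLU
    fmax: 1500.0
    lopt: 0.11
    lslack: 0.13
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.005
    arms:
      - { joint: hipfl, type: const, r0: -0.06, th_max: 0.0, th_ref: 0.25 }
  - name: HFL
    fmax: 2500.0
    lopt: 0.11
    lslack: 0.10
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.005
    arms:
      - { joint: hipfl, type: const, r0: 0.06, th_max: 0.0, th_ref: 0.25 }
  - name: HAB
    fmax: 3000.0
    lopt: 0.09
    lslack: 0.07
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.005
    arms:
      - { joint: hipab, type: const, r0: 0.06, th_max: 0.0, th_ref: 0.05 }
  - name: HAD
    fmax: 4500.0
    lopt: 0.10
    lslack: 0.18
    vmax_rel: 12.0
    tau_act: 0.011
    tau_deact: 0.04
    delay: 0.005
    arms:
      - { joint: hipab, type: const, r0: -0.03, th_max: 0.0, th_ref: 0.0 }
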