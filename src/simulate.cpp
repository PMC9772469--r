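#include "core.h"
using namespace Rcpp;

namespace gp {

// ---------- parameter bundle ----------
struct Params {
  // stretch reflex (normalized fiber-length units)
  double K_l, K_v, h;
  // trunk balance (force-modulated compliant hip) and frontal analog
  double c_ham, c_rf, c_lat;
  // compliant leg positive force feedback
  double g_sol, g_vas, g_gas;
  // knee overextension guard
  double pko_margin, pko_kp, pko_kv;
  // tonic baselines, indexed like the muscle list of one leg
  std::vector<double> s0;
  double delay_ankle, delay_knee, delay_hip;
  double stim_floor, tau_act, tau_deact;
  // balance feedback gains (swing hip target modulation)
  double cd_e_sag, cv_e_sag, cd_l_sag, cv_l_sag;
  double cd_e_fro, cv_e_fro, cd_l_fro, cv_l_fro;
  // high-level control parameters
  double th_hipfl_e, th_knee_e, th_hipfl_l, th_knee_l, th_ankle;
  double t_swing, th_ref_hipfl, a_x, v_init;
  // FSM
  double early_share, min_stance, min_swing_frac, unload_frac,
         pushoff_timeout, t_first_step, flight_warn;
  // fall
  double fall_height_frac, fall_max_tilt;
  // sim
  double dt, control_dt, log_dt, udot_clamp, flfv_guard, tau_cap, lookahead;
  double s_preswing, qdd_cap;
};

static double getd(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) stop(std::string("missing parameter: ") + nm);
  return as<double>(l[nm]);
}

static Params read_params(const List& pl) {
  Params P;
  List sp = pl["spinal"], ba = pl["balance"], co = pl["control"],
       fs = pl["fsm"], fa = pl["fall"], si = pl["sim"];
  P.K_l = getd(sp, "K_l"); P.K_v = getd(sp, "K_v"); P.h = getd(sp, "h");
  P.c_ham = getd(sp, "c_ham"); P.c_rf = getd(sp, "c_rf");
  P.c_lat = getd(pl, "c_lat");
  P.g_sol = getd(sp, "g_sol"); P.g_vas = getd(sp, "g_vas"); P.g_gas = getd(sp, "g_gas");
  P.pko_margin = getd(sp, "pko_margin"); P.pko_kp = getd(sp, "pko_kp");
  P.pko_kv = getd(sp, "pko_kv");
  const char* s0n[10] = {"s0_sol","s0_ta","s0_gas","s0_vas","s0_ham",
                         "s0_rf","s0_glu","s0_hfl","s0_hab","s0_had"};
  P.s0.resize(10);
  for (int i = 0; i < 10; ++i) P.s0[i] = getd(sp, s0n[i]);
  P.delay_ankle = getd(sp, "delay_ankle"); P.delay_knee = getd(sp, "delay_knee");
  P.delay_hip = getd(sp, "delay_hip");
  P.stim_floor = getd(sp, "stim_floor");
  P.tau_act = getd(sp, "tau_act"); P.tau_deact = getd(sp, "tau_deact");
  P.cd_e_sag = getd(ba, "cd_early_sag"); P.cv_e_sag = getd(ba, "cv_early_sag");
  P.cd_l_sag = getd(ba, "cd_late_sag"); P.cv_l_sag = getd(ba, "cv_late_sag");
  P.cd_e_fro = getd(ba, "cd_early_fro"); P.cv_e_fro = getd(ba, "cv_early_fro");
  P.cd_l_fro = getd(ba, "cd_late_fro"); P.cv_l_fro = getd(ba, "cv_late_fro");
  P.th_hipfl_e = getd(co, "theta_hipfl_early"); P.th_knee_e = getd(co, "theta_knee_early");
  P.th_hipfl_l = getd(co, "theta_hipfl_late"); P.th_knee_l = getd(co, "theta_knee_late");
  P.th_ankle = getd(co, "theta_ankle"); P.t_swing = getd(co, "t_swing");
  P.th_ref_hipfl = getd(co, "theta_ref_hipfl"); P.a_x = getd(co, "a_x");
  P.v_init = getd(co, "v_init");
  P.early_share = getd(fs, "early_share"); P.min_stance = getd(fs, "min_stance");
  P.min_swing_frac = getd(fs, "min_swing_frac"); P.unload_frac = getd(fs, "unload_frac");
  P.pushoff_timeout = getd(fs, "pushoff_timeout"); P.t_first_step = getd(fs, "t_first_step");
  P.flight_warn = getd(fs, "flight_warn");
  P.fall_height_frac = getd(fa, "height_frac"); P.fall_max_tilt = getd(fa, "max_tilt");
  P.dt = getd(si, "dt"); P.control_dt = getd(si, "control_dt");
  P.log_dt = getd(si, "log_dt"); P.udot_clamp = getd(si, "udot_clamp");
  P.flfv_guard = getd(si, "fl_fv_guard");
  P.tau_cap = si.containsElementNamed("tau_cap") ? as<double>(si["tau_cap"]) : 150.0;
  P.lookahead = si.containsElementNamed("plan_lookahead")
    ? as<double>(si["plan_lookahead"]) : 0.02;
  P.s_preswing = pl.containsElementNamed("s_preswing")
    ? as<double>(pl["s_preswing"]) : 0.0;
  P.qdd_cap = si.containsElementNamed("qdd_cap") ? as<double>(si["qdd_cap"]) : 60.0;
  return P;
}

// minimal-jerk desired acceleration a small lookahead into a replanned
// quintic from (x0, v0, a0) to (xg, 0, 0) in time T
static double minjerk_acc(double x0, double v0, double a0, double xg,
                          double T, double t_eval) {
  arma::mat33 A = {{T*T*T, T*T*T*T, T*T*T*T*T},
                   {3*T*T, 4*T*T*T, 5*T*T*T*T},
                   {6*T, 12*T*T, 20*T*T*T}};
  arma::vec3 b = {xg - x0 - v0*T - 0.5*a0*T*T, -(v0 + a0*T), -a0};
  arma::vec3 c;
  if (!arma::solve(c, A, b)) return 0.0;
  return a0 + 6*c(0)*t_eval + 12*c(1)*t_eval*t_eval + 20*c(2)*t_eval*t_eval*t_eval;
}

enum Phase { STANCE = 0, EARLY_SWING = 1, LATE_SWING = 2 };

struct LegFSM {
  int phase = STANCE;
  double phase_t = 0;
  double contra_td = -1;   // time of contralateral touchdown during own stance
  bool ever_swung = false;
};

// per-muscle pathway delay (by most distal spanned joint)
static double muscle_delay(const Model& M, const Muscle& mu, const Params& P) {
  bool ank = false, kne = false;
  for (auto& a : mu.arms) {
    for (int leg = 0; leg < 2; ++leg) {
      if (a.qidx == M.j_ankle[leg]) ank = true;
      if (a.qidx == M.j_knee[leg]) kne = true;
    }
  }
  if (ank) return P.delay_ankle;
  if (kne) return P.delay_knee;
  return P.delay_hip;
}

// simple ring buffer over control ticks
struct Ring {
  arma::mat buf; // nsig x nticks
  int pos = 0, n = 1;
  void init(int nsig, int nticks, const arma::vec& x0) {
    n = std::max(nticks, 1);
    buf.set_size(nsig, n);
    for (int i = 0; i < n; ++i) buf.col(i) = x0;
    pos = 0;
  }
  void push(const arma::vec& x) { pos = (pos + 1) % n; buf.col(pos) = x; }
  double read(int sig, int lag) const {
    int i = (pos - lag % n + n) % n;
    return buf(sig, i);
  }
};

} // namespace gp

using namespace gp;

// [[Rcpp::export]]
List wk_simulate(SEXP ptr, List params, double duration, Nullable<List> init,
                 bool log_muscles = true, bool term_on_fall = true,
                 Nullable<NumericVector> sched_times = R_NilValue,
                 Nullable<NumericMatrix> sched_controls = R_NilValue) {
  XPtr<Model> mp(ptr);
  const Model& M = *mp;
  Params P = read_params(params);
  int n_sub = (int)std::round(P.control_dt / P.dt);
  if (std::fabs(n_sub * P.dt - P.control_dt) > 1e-12)
    stop("dt must divide control_dt");
  int log_every = (int)std::round(P.log_dt / P.control_dt);
  if (log_every < 1) log_every = 1;

  int nm = (int)M.muscles.size();       // 20
  int nmh = nm / 2;                     // per leg
  size_t nj = M.joints.size();          // 14

  // ----- initial state -----
  arma::vec q(14, arma::fill::zeros), qd(14, arma::fill::zeros);
  if (init.isNotNull()) {
    List in(init);
    q = as<arma::vec>(in["q"]); qd = as<arma::vec>(in["qd"]);
  } else {
    double z0 = -M.sole_z;
    // straight legs: ankle height + shank + thigh
    const Joint& kneeJ = M.joints[M.j_knee[0]];
    const Joint& ankJ = M.joints[M.j_ankle[0]];
    z0 += -kneeJ.offset(2) - ankJ.offset(2);
    q(2) = z0;
    qd(0) = P.v_init;
  }

  std::vector<MuscleState> ms(nm);
  std::vector<double> S_hold(nm, P.stim_floor);
  for (int i = 0; i < nm; ++i) {
    double lm = muscle_lmtu(M, M.muscles[i], q);
    muscle_init(M, M.muscles[i], ms[i], lm, P.s0[i % nmh]);
    S_hold[i] = P.s0[i % nmh];
  }

  // ----- delays / ring buffers -----
  // signals: per muscle lce_n, vce_n, F (3*nm), per actuated joint q, qd (16),
  // then pitch, roll, d_sag, d_fro, v_sag, v_fro  (6)
  int nsig = 3 * nm + 16 + 6;
  auto sig_lce = [&](int i) { return 3 * i; };
  auto sig_vce = [&](int i) { return 3 * i + 1; };
  auto sig_F = [&](int i) { return 3 * i + 2; };
  auto sig_q = [&](int jq) { return 3 * nm + (jq - 6); };
  auto sig_qd = [&](int jq) { return 3 * nm + 8 + (jq - 6); };
  int sig_pitch = 3 * nm + 16, sig_roll = sig_pitch + 1,
      sig_dsag = sig_pitch + 2, sig_dfro = sig_pitch + 3,
      sig_vsag = sig_pitch + 4, sig_vfro = sig_pitch + 5;

  std::vector<int> mdel(nm);
  int max_del = 1;
  for (int i = 0; i < nm; ++i) {
    mdel[i] = (int)std::round(muscle_delay(M, M.muscles[i], P) / P.control_dt);
    max_del = std::max(max_del, mdel[i]);
  }
  int del_hip = (int)std::round(P.delay_hip / P.control_dt);
  int del_knee = (int)std::round(P.delay_knee / P.control_dt);
  int del_ankle = (int)std::round(P.delay_ankle / P.control_dt);
  max_del = std::max({max_del, del_hip, del_knee, del_ankle});
  auto joint_del = [&](int jq) {
    for (int leg = 0; leg < 2; ++leg) {
      if (jq == M.j_ankle[leg]) return del_ankle;
      if (jq == M.j_knee[leg]) return del_knee;
    }
    return del_hip;
  };

  // FSM contact feedback delayed by the ankle pathway
  std::vector<int> contact_hist_l, contact_hist_r;

  Ring ring;

  // ----- bookkeeping -----
  // legs whose foot starts airborne begin in early swing (mid-gait start)
  LegFSM fsm[2];
  {
    Kin Ki; fk(M, q, qd, Ki);
    std::vector<arma::vec3> efi, eni;
    arma::mat psi; double cxi, cyi; double fzi[2];
    contact_forces(M, Ki, q, qd, efi, eni, psi, cxi, cyi, fzi);
    for (int leg = 0; leg < 2; ++leg) {
      if (fzi[leg] <= 0) {
        fsm[leg].phase = EARLY_SWING;
        fsm[leg].ever_swung = true;
      }
    }
    // double-support start: the lighter-loaded leg is treated as trailing
    // (contralateral touchdown at onset), so pre-swing push-off begins
    if (fsm[0].phase == STANCE && fsm[1].phase == STANCE) {
      int trail = (fzi[0] <= fzi[1]) ? 0 : 1;
      fsm[trail].contra_td = 0.0;
      fsm[trail].phase_t = 0.5; // trailing leg is deep into its stance
    }
    // load-bearing legs start with antigravity muscle tonus, so the body
    // does not sink while the compliant-leg feedback loop charges up
    for (int leg = 0; leg < 2; ++leg) {
      if (fsm[leg].phase != STANCE || fzi[leg] <= 0) continue;
      for (int i = leg * nmh; i < (leg + 1) * nmh; ++i) {
        const std::string& nmn = M.muscles[i].name;
        if (nmn == "VAS" || nmn == "SOL" || nmn == "GLU") {
          if (ms[i].a < 0.3) ms[i].a = 0.3;
        }
      }
    }
  }
  std::vector<double> u(nm, 0), u_prev(nm, 0), udot(nm, 0);
  std::vector<double> a_des_prev(nm, 0);
  bool u_valid[2] = {false, false};
  // planner internal state per leg per joint (hipfl, hipab, knee, ankle):
  // the minimal-jerk plan is integrated forward and softly pulled toward the
  // sensed state each tick, so command generation does not form a high-gain
  // feedback loop through the sensorimotor delays
  double x_plan[2][4] = {{0}}, v_plan[2][4] = {{0}}, a_plan[2][4] = {{0}};
  bool plan_reset[2] = {true, true};
  double lam = 0.05;
  if (params.containsElementNamed("sim")) {
    List si = params["sim"];
    if (si.containsElementNamed("plan_feedback"))
      lam = as<double>(si["plan_feedback"]);
  }

  int n_ticks = (int)std::round(duration / P.control_dt);
  int n_log_max = n_ticks / log_every + 2;
  arma::mat st_log(n_log_max, 29);
  arma::mat grf_log(n_log_max, 6); // fz_l, fz_r, cop_x, cop_y, resid, com_x
  arma::mat mus_log, cmd_log;
  // per muscle: a, F, S, S_STR, S_FMCH, S_CL, S_PKO, lce_n
  if (log_muscles) {
    mus_log.set_size(n_log_max, 8 * nm);
    cmd_log.set_size(n_log_max, 8 + nm); // commanded tau (2x4) + S_tilde
    cmd_log.zeros();
  }
  double last_tau[2][4] = {{0}};
  int n_log = 0;

  std::vector<std::array<double,4>> heel_events; // t, leg, x, y
  std::vector<std::array<double,4>> trans_events; // t, leg, from, to
  std::vector<double> flight_events;
  double fall_t = -1, fall_x = -1; int fall_cause = 0;
  double max_resid = 0;
  int qp_infeasible = 0;
  double stim_min = 1, stim_max = 0;

  bool prev_contact[2] = {true, true};
  double last_dsag = 0, last_dfro = 0;
  double flight_start = -1;
  arma::vec3 com0;
  {
    Kin K0; fk(M, q, qd, K0);
    double mtot; com0 = total_com(M, K0, mtot);
  }

  Kin K;
  std::vector<arma::vec3> ef, en;
  arma::mat ps; double cx, cy; double fz[2];
  std::vector<std::pair<int,double>> arms;
  double body_w = 0;
  for (auto& j : M.joints) body_w += j.m;
  body_w *= M.grav;

  // real-time gait transitions: switch the 8 control parameters at fixed
  // times, irrespective of the gait-cycle state (v_init is ignored after
  // onset; balance and spinal parameters are never touched)
  std::vector<double> sw_t;
  arma::mat sw_c;
  size_t sw_next = 0;
  if (sched_times.isNotNull()) {
    NumericVector st_(sched_times);
    NumericMatrix sc_(sched_controls);
    if ((int)st_.size() != sc_.nrow() || sc_.ncol() < 8)
      stop("schedule shape mismatch");
    sw_t.assign(st_.begin(), st_.end());
    sw_c.set_size(sc_.nrow(), sc_.ncol());
    for (int i = 0; i < sc_.nrow(); ++i)
      for (int j = 0; j < sc_.ncol(); ++j) sw_c(i, j) = sc_(i, j);
  }

  double t = 0;
  bool fallen = false;

  for (int tick = 0; tick < n_ticks && !fallen; ++tick) {
    while (sw_next < sw_t.size() && t >= sw_t[sw_next] - 0.5 * P.control_dt) {
      P.th_hipfl_e = sw_c(sw_next, 0); P.th_knee_e = sw_c(sw_next, 1);
      P.th_hipfl_l = sw_c(sw_next, 2); P.th_knee_l = sw_c(sw_next, 3);
      P.th_ankle = sw_c(sw_next, 4); P.t_swing = sw_c(sw_next, 5);
      P.th_ref_hipfl = sw_c(sw_next, 6); P.a_x = sw_c(sw_next, 7);
      ++sw_next;
    }
    // ---- sense ----
    fk(M, q, qd, K);
    contact_forces(M, K, q, qd, ef, en, ps, cx, cy, fz);
    bool con[2] = {fz[0] > 0, fz[1] > 0};
    arma::vec3 ctr = K.p[M.j_trunk] + K.R[M.j_trunk] * M.joints[M.j_trunk].com;
    arma::vec3 vtr = K.v[M.j_trunk]
      + arma::cross(K.w[M.j_trunk], K.R[M.j_trunk] * M.joints[M.j_trunk].com);
    double dsag = last_dsag, dfro = last_dfro;
    if (std::isfinite(cx)) { dsag = ctr(0) - cx; dfro = ctr(1) - cy; }
    last_dsag = dsag; last_dfro = dfro;

    arma::vec sig(nsig);
    for (int i = 0; i < nm; ++i) {
      sig(sig_lce(i)) = ms[i].lce / M.muscles[i].lopt;
      sig(sig_vce(i)) = ms[i].vce / M.muscles[i].lopt;
      sig(sig_F(i)) = ms[i].F;
    }
    for (int jq = 6; jq < 14; ++jq) {
      sig(sig_q(jq)) = q(jq); sig(sig_qd(jq)) = qd(jq);
    }
    sig(sig_pitch) = q(4); sig(sig_roll) = q(5);
    sig(sig_dsag) = dsag; sig(sig_dfro) = dfro;
    sig(sig_vsag) = vtr(0); sig(sig_vfro) = vtr(1);
    if (tick == 0) ring.init(nsig, max_del + 1, sig);
    else ring.push(sig);
    // FSM feedback: touchdown requires meaningful load, not a graze
    double td_thresh = 0.10 * body_w;
    contact_hist_l.push_back(fz[0] > td_thresh ? 1 : 0);
    contact_hist_r.push_back(fz[1] > td_thresh ? 1 : 0);
    auto delayed_contact = [&](int leg) {
      const std::vector<int>& h = (leg == 0) ? contact_hist_l : contact_hist_r;
      int idx = (int)h.size() - 1 - del_ankle;
      if (idx < 0) idx = 0;
      return h[idx] != 0;
    };

    // ---- events: touchdown (actual contact, rising edge) ----
    for (int leg = 0; leg < 2; ++leg) {
      if (con[leg] && !prev_contact[leg]) {
        // position: lowest sphere of that foot
        int jfoot = M.j_ankle[leg];
        double bx = 0, by = 0, bz = 1e9;
        for (size_t s = 0; s < M.spheres.size(); ++s) {
          if (M.spheres[s].joint != jfoot) continue;
          if (ps(s, 7) < bz) { bz = ps(s, 7); bx = ps(s, 5); by = ps(s, 6); }
        }
        heel_events.push_back({t, (double)leg, bx, by});
      }
      prev_contact[leg] = con[leg];
    }
    // flight anomaly
    if (!con[0] && !con[1]) {
      if (flight_start < 0) flight_start = t;
      else if (t - flight_start > P.flight_warn) {
        flight_events.push_back(flight_start);
        flight_start = t + 1e9; // report once
      }
    } else flight_start = -1;

    // ---- fall detection ----
    double mtot; arma::vec3 com = total_com(M, K, mtot);
    if (ctr(2) < P.fall_height_frac * M.standing_z ||
        std::fabs(q(4)) > P.fall_max_tilt || std::fabs(q(5)) > P.fall_max_tilt) {
      fall_t = t; fall_x = com(0) - com0(0); fall_cause = 1;
      if (std::fabs(q(4)) > P.fall_max_tilt || std::fabs(q(5)) > P.fall_max_tilt)
        fall_cause = 2;
      fallen = true;
    }
    if (!q.is_finite() || !qd.is_finite()) {
      fall_t = t; fall_x = com(0) - com0(0); fall_cause = 3;
      fallen = true;
    }

    // ---- FSM ----
    for (int leg = 0; leg < 2 && !fallen; ++leg) {
      LegFSM& F = fsm[leg];
      int contra = 1 - leg;
      int old = F.phase;
      bool own_c = delayed_contact(leg), con_c = delayed_contact(contra);
      if (F.phase == STANCE) {
        bool contra_loaded = fz[contra] > 0.35 * body_w;
        if (fsm[contra].phase == STANCE && F.contra_td < 0 &&
            fsm[contra].phase_t < F.phase_t && con_c)
          F.contra_td = t;
        bool kick = (!F.ever_swung && leg == 0 && t >= P.t_first_step && con_c);
        bool unloaded = fz[leg] < P.unload_frac * body_w;
        bool pushoff = (F.contra_td >= 0) &&
          (unloaded || (t - F.contra_td) > P.pushoff_timeout);
        if ((kick || (contra_loaded && pushoff)) && F.phase_t >= P.min_stance &&
            fsm[contra].phase == STANCE) {
          F.phase = EARLY_SWING; F.phase_t = 0; F.contra_td = -1;
          F.ever_swung = true;
          plan_reset[leg] = true;
          u_valid[leg] = false;
        }
      } else if (F.phase == EARLY_SWING) {
        if (F.phase_t >= P.early_share * P.t_swing) {
          F.phase = LATE_SWING;
        } else if (own_c && F.phase_t >= P.min_swing_frac * P.t_swing) {
          F.phase = STANCE; F.phase_t = 0; F.contra_td = -1; u_valid[leg] = false;
        }
      } else { // LATE_SWING
        if (own_c && F.phase_t >= P.min_swing_frac * P.t_swing) {
          F.phase = STANCE; F.phase_t = 0; F.contra_td = -1; u_valid[leg] = false;
        }
      }
      if (F.phase != old)
        trans_events.push_back({t, (double)leg, (double)old, (double)F.phase});
    }
    if (fallen) break;

    // ---- descending commands and stimulations ----
    std::vector<double> S_STR(nm, 0), S_FMCH(nm, 0), S_CL(nm, 0), S_PKO(nm, 0);
    std::vector<double> S_tilde(nm, 0);

    for (int leg = 0; leg < 2; ++leg) {
      LegFSM& F = fsm[leg];
      int jfl = M.j_hipfl[leg], jab = M.j_hipab[leg],
          jkn = M.j_knee[leg], jan = M.j_ankle[leg];
      int m0 = leg * nmh;
      // delayed sensed joint state of this leg
      double qs[4], qds[4]; // hipfl, hipab, knee, ankle
      int jqs[4] = {jfl, jab, jkn, jan};
      for (int k = 0; k < 4; ++k) {
        int lag = joint_del(jqs[k]);
        qs[k] = ring.read(sig_q(jqs[k]), lag);
        qds[k] = ring.read(sig_qd(jqs[k]), lag);
      }
      // delayed balance signals (hip/trunk pathway)
      double pitch_h = ring.read(sig_pitch, del_hip);
      double roll_h = ring.read(sig_roll, del_hip);
      double dsag_h = ring.read(sig_dsag, del_hip);
      double dfro_h = ring.read(sig_dfro, del_hip);
      double vsag_h = ring.read(sig_vsag, del_hip);
      double vfro_h = ring.read(sig_vfro, del_hip);

      if (F.phase == EARLY_SWING || F.phase == LATE_SWING) {
        bool early = (F.phase == EARLY_SWING);
        double sgn = (leg == 0) ? 1.0 : -1.0; // frontal: + = outward for left
        double cd_s = early ? P.cd_e_sag : P.cd_l_sag;
        double cv_s = early ? P.cv_e_sag : P.cv_l_sag;
        double cd_f = early ? P.cd_e_fro : P.cd_l_fro;
        double cv_f = early ? P.cv_e_fro : P.cv_l_fro;
        double th_hip = (early ? P.th_hipfl_e : P.th_hipfl_l)
          + cd_s * dsag_h + cv_s * vsag_h - pitch_h;
        double th_ab = sgn * (cd_f * dfro_h + cv_f * vfro_h - roll_h);
        double th_kne = early ? P.th_knee_e : P.th_knee_l;
        double T_end = early ? P.early_share * P.t_swing : P.t_swing;
        double T_rem = T_end - F.phase_t;
        double T_rem_ank = P.t_swing - F.phase_t;
        // desired accelerations (hipfl, hipab, knee, ankle)
        double qdd_des[4];
        double tgt[4] = {th_hip, th_ab, th_kne, P.th_ankle};
        double Trem[4] = {T_rem, T_rem, T_rem, T_rem_ank};
        if (plan_reset[leg]) {
          for (int k = 0; k < 4; ++k) {
            x_plan[leg][k] = qs[k]; v_plan[leg][k] = qds[k]; a_plan[leg][k] = 0;
          }
          plan_reset[leg] = false;
        }
        for (int k = 0; k < 4; ++k) {
          x_plan[leg][k] += lam * (qs[k] - x_plan[leg][k]);
          v_plan[leg][k] += lam * (qds[k] - v_plan[leg][k]);
          if (Trem[k] < P.control_dt) {
            qdd_des[k] = 0; a_plan[leg][k] = 0;
            v_plan[leg][k] = 0; x_plan[leg][k] = tgt[k];
          } else {
            double te = std::min(P.lookahead, 0.5 * Trem[k]);
            double add = minjerk_acc(x_plan[leg][k], v_plan[leg][k],
                                     a_plan[leg][k], tgt[k], Trem[k], te);
            if (add > P.qdd_cap) add = P.qdd_cap;
            if (add < -P.qdd_cap) add = -P.qdd_cap;
            qdd_des[k] = add;
            x_plan[leg][k] += v_plan[leg][k] * P.control_dt
              + 0.5 * add * P.control_dt * P.control_dt;
            v_plan[leg][k] += add * P.control_dt;
            a_plan[leg][k] = add;
          }
        }
        // swing inverse dynamics on the sensed configuration
        arma::vec qh = q, qdh = qd;
        for (int k = 0; k < 4; ++k) { qh(jqs[k]) = qs[k]; qdh(jqs[k]) = qds[k]; }
        arma::vec tau_sw = swing_inverse_dynamics(
          M, qh, qdh, leg,
          arma::vec({qdd_des[0], qdd_des[1], qdd_des[2], qdd_des[3]}), true);
        tau_sw = arma::clamp(tau_sw, -P.tau_cap, P.tau_cap);
        // force distribution over this leg's muscles
        arma::mat Rm(4, nmh, arma::fill::zeros);
        for (int i = 0; i < nmh; ++i) {
          muscle_arms(M, M.muscles[m0 + i], qh, arms);
          for (auto& a : arms) {
            for (int r = 0; r < 4; ++r) if (a.first == jqs[r]) Rm(r, i) = a.second;
          }
        }
        // planned configuration for the threshold-shift commands
        arma::vec qp_full = qh;
        for (int k = 0; k < 4; ++k) qp_full(jqs[k]) = x_plan[leg][k];
        // force distribution bounded by the sensed force-generating capacity
        arma::vec cap(nmh), lce_s(nmh), vce_s(nmh);
        for (int i = 0; i < nmh; ++i) {
          const Muscle& mu = M.muscles[m0 + i];
          lce_s(i) = ring.read(sig_lce(m0 + i), mdel[m0 + i]);
          vce_s(i) = ring.read(sig_vce(m0 + i), mdel[m0 + i]);
          double g = fl_curve(M, mu, lce_s(i) * mu.lopt) *
                     fv_curve(M, mu, vce_s(i) * mu.lopt);
          if (g < P.flfv_guard) g = P.flfv_guard;
          cap(i) = mu.Fmax * g;
        }
        bool feas;
        arma::vec Fm = qp_min_force_bounded(Rm, tau_sw, &cap, feas);
        if (!feas) ++qp_infeasible;
        for (int k = 0; k < 4; ++k) last_tau[leg][k] = tau_sw(k);
        for (int i = 0; i < nmh; ++i) {
          double a_des = std::min(1.0, std::max(0.0, Fm(i) / cap(i)));
          // invert first-order activation dynamics (lead compensation)
          double adot = u_valid[leg]
            ? (a_des - a_des_prev[m0 + i]) / P.control_dt : 0.0;
          double tau_a = (adot >= 0) ? P.tau_act : P.tau_deact;
          double St = std::min(1.0, std::max(0.0, a_des + tau_a * adot));
          a_des_prev[m0 + i] = a_des;
          S_tilde[m0 + i] = St;
          // threshold shift from the PLANNED fiber length: the stretch
          // reflex then acts as a spinal servo around the motor plan
          const Muscle& mu = M.muscles[m0 + i];
          double lmtu_p = muscle_lmtu(M, mu, qp_full);
          double eps = M.see_eps_ref * std::sqrt(std::min(1.0, Fm(i) / mu.Fmax));
          double lce_p = lmtu_p - mu.lslack * (1.0 + eps);
          double lo = 0.3 * mu.lopt, hi = 1.7 * mu.lopt;
          if (lce_p < lo) lce_p = lo;
          if (lce_p > hi) lce_p = hi;
          double un = (St + P.h) / P.K_l - lce_p / mu.lopt;
          double ud = u_valid[leg] ? (un - u_prev[m0 + i]) / P.control_dt : 0.0;
          if (ud > P.udot_clamp) ud = P.udot_clamp;
          if (ud < -P.udot_clamp) ud = -P.udot_clamp;
          u[m0 + i] = un; udot[m0 + i] = ud;
          double s = P.K_l * (lce_s(i) + un) + P.K_v * (vce_s(i) + ud) - P.h;
          S_STR[m0 + i] = (s > 0) ? s : 0;
        }
        u_valid[leg] = true;
      } else { // STANCE
        // propulsion: constrained stance inverse kinematics on sensed config
        arma::vec qh = q, qdh = qd;
        for (int k = 0; k < 4; ++k) { qh(jqs[k]) = qs[k]; qdh(jqs[k]) = qds[k]; }
        Kin Kh; fk(M, qh, qdh, Kh);
        arma::vec3 pb = Kh.p[jan] + Kh.R[jan] * arma::vec3({M.ball_x, 0, M.sole_z});
        arma::mat J, Mc;
        chain_jacobian_mass(M, Kh, leg, pb, J, Mc);
        arma::mat A(4, 5);
        A.row(0) = J.row(0);        // j_x
        A.row(1) = J.row(5);        // j_rz
        A.row(2) = Mc.row(4);       // m_ball
        A.row(3) = Mc.row(1);       // m_hipab
        arma::vec b = {P.a_x, 0, 0, 0};
        arma::mat Ap;
        bool ok = arma::pinv(Ap, A);
        if (!ok) ok = arma::pinv(Ap, A, 1e-6);
        arma::vec thdd = Ap * b;
        double resid = arma::norm(A * thdd - b, "inf");
        if (resid > max_resid) max_resid = resid;
        arma::vec tau5 = Mc * thdd;
        arma::vec tau_st = {tau5(0), tau5(1), tau5(2), tau5(3)};
        tau_st = arma::clamp(tau_st, -P.tau_cap, P.tau_cap);
        arma::mat Rm(4, nmh, arma::fill::zeros);
        for (int i = 0; i < nmh; ++i) {
          muscle_arms(M, M.muscles[m0 + i], qh, arms);
          for (auto& a : arms) {
            for (int r = 0; r < 4; ++r) if (a.first == jqs[r]) Rm(r, i) = a.second;
          }
        }
        arma::vec cap(nmh), lce_s(nmh), vce_s(nmh);
        for (int i = 0; i < nmh; ++i) {
          const Muscle& mu = M.muscles[m0 + i];
          lce_s(i) = ring.read(sig_lce(m0 + i), mdel[m0 + i]);
          vce_s(i) = ring.read(sig_vce(m0 + i), mdel[m0 + i]);
          double g = fl_curve(M, mu, lce_s(i) * mu.lopt) *
                     fv_curve(M, mu, vce_s(i) * mu.lopt);
          if (g < P.flfv_guard) g = P.flfv_guard;
          cap(i) = mu.Fmax * g;
        }
        bool feas;
        arma::vec Fm = qp_min_force_bounded(Rm, tau_st, &cap, feas);
        if (!feas) ++qp_infeasible;
        for (int k = 0; k < 4; ++k) last_tau[leg][k] = tau_st(k);
        // leg force estimate for the balance reflexes (Golgi tendon feedback)
        int i_sol = -1, i_vas = -1, i_ham = -1, i_rf = -1, i_gas = -1,
            i_hab = -1, i_had = -1;
        for (int i = 0; i < nmh; ++i) {
          const std::string& nmn = M.muscles[m0 + i].name;
          if (nmn == "SOL") i_sol = i; else if (nmn == "VAS") i_vas = i;
          else if (nmn == "HAM") i_ham = i; else if (nmn == "RF") i_rf = i;
          else if (nmn == "GAS") i_gas = i; else if (nmn == "HAB") i_hab = i;
          else if (nmn == "HAD") i_had = i;
        }
        if (i_sol < 0 || i_vas < 0 || i_ham < 0 || i_rf < 0 || i_gas < 0 ||
            i_hab < 0 || i_had < 0)
          stop("model must define SOL, VAS, GAS, HAM, RF, HAB, HAD muscles");
        double F_sol = ring.read(sig_F(m0 + i_sol), mdel[m0 + i_sol]);
        double F_vas = ring.read(sig_F(m0 + i_vas), mdel[m0 + i_vas]);
        double m_sol = 0, m_vas = 0;
        muscle_arms(M, M.muscles[m0 + i_sol], qh, arms);
        for (auto& a : arms) if (a.first == jan) m_sol = std::fabs(a.second);
        muscle_arms(M, M.muscles[m0 + i_vas], qh, arms);
        for (auto& a : arms) if (a.first == jkn) m_vas = std::fabs(a.second);
        double F_s = (F_vas * m_vas + F_sol * m_sol) / 0.032;
        // FMCH: biarticular hip muscles balance the trunk
        double th_err = qs[0] - P.th_ref_hipfl; // sensed stance hip flexion
        S_FMCH[m0 + i_ham] = P.c_ham * F_s * std::max(0.0, th_err);
        S_FMCH[m0 + i_rf] = P.c_rf * F_s * std::max(0.0, -th_err);
        // frontal-plane analog on hip ab/adductors (fixed gain)
        double sgn = (leg == 0) ? 1.0 : -1.0;
        S_FMCH[m0 + i_hab] = P.c_lat * F_s * std::max(0.0, sgn * roll_h);
        S_FMCH[m0 + i_had] = P.c_lat * F_s * std::max(0.0, -sgn * roll_h);
        // compliant leg: positive force feedback on anti-gravity muscles
        S_CL[m0 + i_sol] = P.g_sol * F_sol;
        S_CL[m0 + i_vas] = P.g_vas * F_vas;
        S_CL[m0 + i_gas] = P.g_gas * ring.read(sig_F(m0 + i_gas), mdel[m0 + i_gas]);
        // pre-swing push-off: during double support the trailing leg
        // flexes the knee and plantarflexes through the gastrocnemius,
        // unloading the foot before swing initiation; the knee extensor's
        // force feedback is suppressed so the leg can shorten
        if (F.contra_td >= 0) {
          S_CL[m0 + i_gas] += P.s_preswing;
          S_CL[m0 + i_vas] = 0;
        }
        // knee overextension guard on knee flexors
        double kq = qs[2], kqd = qds[2];
        if (kq < P.pko_margin && kqd < 0) {
          double spk = (P.pko_margin - kq) * (P.pko_kp + P.pko_kv * (-kqd));
          S_PKO[m0 + i_ham] += spk;
          S_PKO[m0 + i_gas] += spk;
        }
        for (int i = 0; i < nmh; ++i) {
          double a_des = std::min(1.0, std::max(0.0, Fm(i) / cap(i)));
          double adot = u_valid[leg]
            ? (a_des - a_des_prev[m0 + i]) / P.control_dt : 0.0;
          double tau_a = (adot >= 0) ? P.tau_act : P.tau_deact;
          double St = std::min(1.0, std::max(0.0, a_des + tau_a * adot));
          a_des_prev[m0 + i] = a_des;
          S_tilde[m0 + i] = St;
          double un = (St + P.h) / P.K_l - lce_s(i);
          double ud = u_valid[leg] ? (un - u_prev[m0 + i]) / P.control_dt : 0.0;
          if (ud > P.udot_clamp) ud = P.udot_clamp;
          if (ud < -P.udot_clamp) ud = -P.udot_clamp;
          u[m0 + i] = un; udot[m0 + i] = ud;
          double s = P.K_l * (lce_s(i) + un) + P.K_v * (vce_s(i) + ud) - P.h;
          S_STR[m0 + i] = (s > 0) ? s : 0;
        }
        u_valid[leg] = true;
      }
    }
    for (int i = 0; i < nm; ++i) u_prev[i] = u[i];

    // integrate total stimulation (tonic baseline + reflex components)
    for (int i = 0; i < nm; ++i) {
      double s = P.s0[i % nmh] + S_STR[i] + S_FMCH[i] + S_CL[i] + S_PKO[i];
      if (s < 0) s = 0;
      if (s < P.stim_floor) s = P.stim_floor;
      if (s > 1) s = 1;
      S_hold[i] = s;
      if (s < stim_min) stim_min = s;
      if (s > stim_max) stim_max = s;
    }

    // ---- log ----
    if (tick % log_every == 0) {
      st_log(n_log, 0) = t;
      for (int i = 0; i < 14; ++i) {
        st_log(n_log, 1 + i) = q(i);
        st_log(n_log, 15 + i) = qd(i);
      }
      grf_log(n_log, 0) = fz[0]; grf_log(n_log, 1) = fz[1];
      grf_log(n_log, 2) = cx; grf_log(n_log, 3) = cy;
      grf_log(n_log, 4) = max_resid; grf_log(n_log, 5) = com(0);
      if (log_muscles) {
        for (int i = 0; i < nm; ++i) {
          mus_log(n_log, 8 * i + 0) = ms[i].a;
          mus_log(n_log, 8 * i + 1) = ms[i].F;
          mus_log(n_log, 8 * i + 2) = S_hold[i];
          mus_log(n_log, 8 * i + 3) = S_STR[i];
          mus_log(n_log, 8 * i + 4) = S_FMCH[i];
          mus_log(n_log, 8 * i + 5) = S_CL[i];
          mus_log(n_log, 8 * i + 6) = S_PKO[i];
          mus_log(n_log, 8 * i + 7) = ms[i].lce / M.muscles[i].lopt;
        }
        for (int leg = 0; leg < 2; ++leg)
          for (int k = 0; k < 4; ++k)
            cmd_log(n_log, 4 * leg + k) = last_tau[leg][k];
        for (int i = 0; i < nm; ++i) cmd_log(n_log, 8 + i) = S_tilde[i];
      }
      ++n_log;
    }

    // ---- integrate n_sub physics substeps ----
    for (int sub = 0; sub < n_sub; ++sub) {
      Kin Ks; fk(M, q, qd, Ks);
      arma::vec tau_q(nj, arma::fill::zeros);
      for (int i = 0; i < nm; ++i) {
        const Muscle& mu = M.muscles[i];
        double lm = muscle_lmtu(M, mu, q);
        muscle_step(M, mu, ms[i], S_hold[i], lm, P.dt);
        muscle_arms(M, mu, q, arms);
        for (auto& a : arms) tau_q(a.first) += a.second * ms[i].F;
      }
      // anatomical soft stops and passive joint damping
      for (int jq = 6; jq < 14; ++jq) {
        tau_q(jq) -= M.joint_damping * qd(jq);
        if (q(jq) > M.qmax[jq])
          tau_q(jq) += -M.k_limit * (q(jq) - M.qmax[jq]) - M.d_limit * qd(jq);
        else if (q(jq) < M.qmin[jq])
          tau_q(jq) += -M.k_limit * (q(jq) - M.qmin[jq]) - M.d_limit * qd(jq);
      }
      std::vector<arma::vec3> ef2, en2;
      arma::mat ps2; double cx2, cy2; double fz2[2];
      contact_forces(M, Ks, q, qd, ef2, en2, ps2, cx2, cy2, fz2);
      arma::vec bias = rnea(M, q, qd, arma::vec(nj, arma::fill::zeros), true,
                            &ef2, &en2);
      arma::mat Mm = crba(M, Ks);
      arma::vec qdd;
      bool oks = arma::solve(qdd, Mm, tau_q - bias,
                             arma::solve_opts::likely_sympd);
      if (!oks || !qdd.is_finite()) {
        double mtot2; arma::vec3 com2 = total_com(M, Ks, mtot2);
        fall_t = t; fall_x = com2(0) - com0(0); fall_cause = 3; fallen = true;
        break;
      }
      qd += P.dt * qdd;
      q += P.dt * qd;
      t += P.dt;
    }
    for (int leg = 0; leg < 2; ++leg) fsm[leg].phase_t += P.control_dt;
  }

  // final com displacement
  double x_walked;
  {
    Kin Kf; fk(M, q, qd, Kf);
    double mt; arma::vec3 comf = total_com(M, Kf, mt);
    x_walked = comf(0) - com0(0);
  }

  st_log.resize(n_log, 29);
  grf_log.resize(n_log, 6);
  if (log_muscles) { mus_log.resize(n_log, 8 * nm); cmd_log.resize(n_log, 8 + nm); }

  arma::mat heel(heel_events.size(), 4), trans(trans_events.size(), 4);
  for (size_t i = 0; i < heel_events.size(); ++i)
    for (int k = 0; k < 4; ++k) heel(i, k) = heel_events[i][k];
  for (size_t i = 0; i < trans_events.size(); ++i)
    for (int k = 0; k < 4; ++k) trans(i, k) = trans_events[i][k];

  SEXP fall = R_NilValue;
  if (fall_t >= 0)
    fall = List::create(_["time"] = fall_t, _["x_fall"] = fall_x,
                        _["cause"] = fall_cause);

  return List::create(
    _["states"] = st_log, _["grf"] = grf_log, _["muscle_log"] = mus_log,
    _["cmd_log"] = cmd_log,
    _["heel_strikes"] = heel, _["transitions"] = trans,
    _["fall"] = fall, _["flight_anomalies"] = flight_events,
    _["t_end"] = t, _["x_walked"] = x_walked,
    _["max_propulsion_residual"] = max_resid,
    _["qp_infeasible"] = qp_infeasible,
    _["stim_range"] = NumericVector::create(stim_min, stim_max),
    _["final_q"] = q, _["final_qd"] = qd);
}
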