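#include "core.h"
using namespace Rcpp;

// [[Rcpp::export]]
SEXP wk_build_model(List cfg) {
  gp::Model* m = new gp::Model(gp::build_model(cfg));
  XPtr<gp::Model> p(m, true);
  return p;
}

// [[Rcpp::export]]
List wk_model_info(SEXP ptr) {
  XPtr<gp::Model> m(ptr);
  double mass = 0;
  for (auto& j : m->joints) mass += j.m;
  CharacterVector mn; IntegerVector ml;
  for (auto& mu : m->muscles) { mn.push_back(mu.name); ml.push_back(mu.leg); }
  return List::create(_["n_dof"] = (int)m->joints.size(),
                      _["total_mass"] = mass,
                      _["standing_z"] = m->standing_z,
                      _["muscle_names"] = mn, _["muscle_leg"] = ml,
                      _["n_spheres"] = (int)m->spheres.size());
}

// [[Rcpp::export]]
arma::vec wk_rnea(SEXP ptr, arma::vec q, arma::vec qd, arma::vec qdd, bool gravity) {
  XPtr<gp::Model> m(ptr);
  return gp::rnea(*m, q, qd, qdd, gravity);
}

// [[Rcpp::export]]
arma::mat wk_mass_matrix(SEXP ptr, arma::vec q) {
  XPtr<gp::Model> m(ptr);
  return gp::mass_matrix(*m, q);
}

// [[Rcpp::export]]
arma::vec wk_forward_dynamics(SEXP ptr, arma::vec q, arma::vec qd, arma::vec tau8,
                              bool with_contact) {
  XPtr<gp::Model> m(ptr);
  if (!q.is_finite() || !qd.is_finite() || !tau8.is_finite())
    stop("non-finite state or torque input");
  return gp::forward_dynamics(*m, q, qd, tau8, with_contact);
}

// [[Rcpp::export]]
double wk_energy(SEXP ptr, arma::vec q, arma::vec qd) {
  XPtr<gp::Model> m(ptr);
  return gp::energy(*m, q, qd);
}

// [[Rcpp::export]]
List wk_contact(SEXP ptr, arma::vec q, arma::vec qd) {
  XPtr<gp::Model> m(ptr);
  gp::Kin K; gp::fk(*m, q, qd, K);
  std::vector<arma::vec3> ef, en;
  arma::mat ps; double cx, cy; double fz[2];
  gp::contact_forces(*m, K, q, qd, ef, en, ps, cx, cy, fz);
  return List::create(_["per_sphere"] = ps, _["cop_x"] = cx, _["cop_y"] = cy,
                      _["fz_left"] = fz[0], _["fz_right"] = fz[1]);
}

// [[Rcpp::export]]
List wk_fk(SEXP ptr, arma::vec q, arma::vec qd) {
  XPtr<gp::Model> m(ptr);
  gp::Kin K; gp::fk(*m, q, qd, K);
  size_t n = m->joints.size();
  arma::mat P(n, 3), A(n, 3), W(n, 3), V(n, 3), C(n, 3);
  for (size_t i = 0; i < n; ++i) {
    P.row(i) = K.p[i].t(); A.row(i) = K.ax[i].t();
    W.row(i) = K.w[i].t(); V.row(i) = K.v[i].t();
    C.row(i) = (K.p[i] + K.R[i] * m->joints[i].com).t();
  }
  double mass; arma::vec3 com = gp::total_com(*m, K, mass);
  arma::vec3 ctr = K.p[5] + K.R[5] * m->joints[5].com;
  arma::vec3 vtr = K.v[5] + arma::cross(K.w[5], K.R[5] * m->joints[5].com);
  return List::create(_["p_joint"] = P, _["axis"] = A, _["w"] = W, _["v"] = V,
                      _["com_body"] = C, _["com_total"] = com,
                      _["trunk_com"] = ctr, _["trunk_com_vel"] = vtr,
                      _["trunk_w"] = K.w[5]);
}

// [[Rcpp::export]]
List wk_chain(SEXP ptr, arma::vec q, arma::vec qd, int side) {
  XPtr<gp::Model> m(ptr);
  gp::Kin K; gp::fk(*m, q, qd, K);
  int jan = m->j_ankle[side];
  arma::vec3 pb = K.p[jan] + K.R[jan] * arma::vec3({m->ball_x, 0, m->sole_z});
  arma::mat J, Mc;
  gp::chain_jacobian_mass(*m, K, side, pb, J, Mc);
  return List::create(_["J"] = J, _["M_chain"] = Mc, _["p_ball"] = pb);
}

// [[Rcpp::export]]
arma::vec wk_swing_id(SEXP ptr, arma::vec q, arma::vec qd, int side,
                      arma::vec qdd_des, bool base_motion) {
  XPtr<gp::Model> m(ptr);
  return gp::swing_inverse_dynamics(*m, q, qd, side, qdd_des, base_motion);
}

// [[Rcpp::export]]
List wk_muscle_geometry(SEXP ptr, arma::vec q) {
  XPtr<gp::Model> m(ptr);
  int nm = (int)m->muscles.size();
  arma::vec lm(nm);
  arma::mat R(8, nm, arma::fill::zeros); // rows: q indices 6..13
  std::vector<std::pair<int,double>> arms;
  for (int i = 0; i < nm; ++i) {
    lm(i) = gp::muscle_lmtu(*m, m->muscles[i], q);
    gp::muscle_arms(*m, m->muscles[i], q, arms);
    for (auto& a : arms) R(a.first - 6, i) = a.second;
  }
  return List::create(_["lmtu"] = lm, _["R"] = R);
}

// [[Rcpp::export]]
List wk_muscle_step(List mtu, List state, double S, double lmtu, double dt,
                    List hill) {
  gp::Model M; // only the Hill shape constants are used
  M.fl_w = as<double>(hill["fl_w"]); M.fl_c = as<double>(hill["fl_c"]);
  M.fv_K = as<double>(hill["fv_K"]); M.fv_N = as<double>(hill["fv_N"]);
  M.see_eps_ref = as<double>(hill["see_eps_ref"]);
  M.pe_w = as<double>(hill["pe_w"]);
  gp::Muscle mu;
  mu.Fmax = as<double>(mtu["fmax"]); mu.lopt = as<double>(mtu["lopt"]);
  mu.lslack = as<double>(mtu["lslack"]);
  mu.vmax = as<double>(mtu["vmax_rel"]) * mu.lopt;
  mu.tau_act = as<double>(mtu["tau_act"]); mu.tau_deact = as<double>(mtu["tau_deact"]);
  gp::MuscleState st;
  st.a = as<double>(state["a"]); st.lce = as<double>(state["lce"]);
  st.vce = as<double>(state["vce"]); st.F = 0;
  gp::muscle_step(M, mu, st, S, lmtu, dt);
  double fl = gp::fl_curve(M, mu, st.lce), fv = gp::fv_curve(M, mu, st.vce);
  return List::create(_["a"] = st.a, _["lce"] = st.lce, _["vce"] = st.vce,
                      _["F"] = st.F, _["fl"] = fl, _["fv"] = fv);
}

// [[Rcpp::export]]
List wk_muscle_init(List mtu, double lmtu, double a0, List hill) {
  gp::Model M;
  M.fl_w = as<double>(hill["fl_w"]); M.fl_c = as<double>(hill["fl_c"]);
  M.fv_K = as<double>(hill["fv_K"]); M.fv_N = as<double>(hill["fv_N"]);
  M.see_eps_ref = as<double>(hill["see_eps_ref"]);
  M.pe_w = as<double>(hill["pe_w"]);
  gp::Muscle mu;
  mu.Fmax = as<double>(mtu["fmax"]); mu.lopt = as<double>(mtu["lopt"]);
  mu.lslack = as<double>(mtu["lslack"]);
  mu.vmax = as<double>(mtu["vmax_rel"]) * mu.lopt;
  mu.tau_act = as<double>(mtu["tau_act"]); mu.tau_deact = as<double>(mtu["tau_deact"]);
  gp::MuscleState st;
  gp::muscle_init(M, mu, st, lmtu, a0);
  return List::create(_["a"] = st.a, _["lce"] = st.lce, _["vce"] = st.vce,
                      _["F"] = st.F);
}

// [[Rcpp::export]]
List wk_qp(arma::mat R, arma::vec tau) {
  bool feasible;
  arma::vec F = gp::qp_min_force(R, tau, feasible);
  return List::create(_["F"] = F, _["feasible"] = feasible,
                      _["residual"] = arma::norm(R * F - tau));
}

// Passive (muscle-free) fixed-step integration; used by the physics tests.
// Returns the final state, an energy trace, and the time-integral of the
// ground contact forces (for momentum-balance checks).
// [[Rcpp::export]]
List wk_passive_sim(SEXP ptr, arma::vec q, arma::vec qd, double dt, int n,
                    bool contact, int energy_every = 100) {
  XPtr<gp::Model> m(ptr);
  size_t nj = m->joints.size();
  std::vector<double> E; E.reserve(n / energy_every + 2);
  arma::vec3 imp(arma::fill::zeros);
  arma::vec zero(nj, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    if (i % energy_every == 0) E.push_back(gp::energy(*m, q, qd));
    arma::vec bias;
    gp::Kin K; gp::fk(*m, q, qd, K);
    if (contact) {
      std::vector<arma::vec3> ef, en;
      arma::mat ps; double cx, cy; double fz[2];
      gp::contact_forces(*m, K, q, qd, ef, en, ps, cx, cy, fz);
      for (size_t s = 0; s < ps.n_rows; ++s) {
        imp(0) += ps(s, 0) * dt; imp(1) += ps(s, 1) * dt; imp(2) += ps(s, 2) * dt;
      }
      bias = gp::rnea(*m, q, qd, zero, true, &ef, &en);
    } else {
      bias = gp::rnea(*m, q, qd, zero, true);
    }
    arma::mat Mm = gp::crba(*m, K);
    arma::vec qdd = arma::solve(Mm, -bias, arma::solve_opts::likely_sympd);
    qd += dt * qdd;
    q += dt * qd;
  }
  E.push_back(gp::energy(*m, q, qd));
  // whole-body momentum
  gp::Kin K; gp::fk(*m, q, qd, K);
  arma::vec3 p(arma::fill::zeros);
  for (size_t i = 0; i < nj; ++i) {
    const gp::Joint& J = m->joints[i];
    if (J.m <= 0) continue;
    arma::vec3 cw = K.R[i] * J.com;
    arma::vec3 vc = K.v[i] + arma::cross(K.w[i], cw);
    p += J.m * vc;
  }
  return List::create(_["q"] = q, _["qd"] = qd, _["energy"] = E,
                      _["impulse"] = imp, _["momentum"] = p);
}

// [[Rcpp::export]]
List wk_qp_bounded(arma::mat R, arma::vec tau, arma::vec ub) {
  bool feasible;
  arma::vec F = gp::qp_min_force_bounded(R, tau, &ub, feasible);
  return List::create(_["F"] = F, _["feasible"] = feasible,
                      _["residual"] = arma::norm(R * F - tau));
}

// [[Rcpp::export]]
arma::vec wk_fl_fv(double lce, double vce, List mtu, List hill) {
  gp::Model M;
  M.fl_w = as<double>(hill["fl_w"]); M.fl_c = as<double>(hill["fl_c"]);
  M.fv_K = as<double>(hill["fv_K"]); M.fv_N = as<double>(hill["fv_N"]);
  M.see_eps_ref = as<double>(hill["see_eps_ref"]); M.pe_w = as<double>(hill["pe_w"]);
  gp::Muscle mu;
  mu.lopt = as<double>(mtu["lopt"]);
  mu.vmax = as<double>(mtu["vmax_rel"]) * mu.lopt;
  return arma::vec({gp::fl_curve(M, mu, lce), gp::fv_curve(M, mu, vce)});
}
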