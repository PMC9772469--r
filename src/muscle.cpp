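#include "core.h"

namespace gp {

// Muscle-tendon length as a function of the spanned joint angles
// (tendon-excursion convention: moment arm R = -d l_mtu / d theta, with
// positive arm meaning the muscle generates positive joint torque).
double muscle_lmtu(const Model& M, const Muscle& mu, const arma::vec& q) {
  double l = mu.lslack + mu.lopt;
  for (const ArmSpec& a : mu.arms) {
    double th = q(a.qidx);
    if (a.type == 0) {
      l += -a.r0 * (th - a.th_ref);
    } else {
      l += -a.r0 * (std::sin(th - a.th_max) - std::sin(a.th_ref - a.th_max));
    }
  }
  return l;
}

void muscle_arms(const Model& M, const Muscle& mu, const arma::vec& q,
                 std::vector<std::pair<int,double>>& out) {
  out.clear();
  for (const ArmSpec& a : mu.arms) {
    double r = (a.type == 0) ? a.r0 : a.r0 * std::cos(q(a.qidx) - a.th_max);
    out.push_back({a.qidx, r});
  }
}

// Gaussian-like active force-length; maximum 1 at l_opt
double fl_curve(const Model& M, const Muscle& mu, double lce) {
  double x = std::fabs((lce - mu.lopt) / (mu.lopt * M.fl_w));
  return std::exp(M.fl_c * x * x * x);
}

// Hyperbolic force-velocity; vce > 0 is lengthening, f_v(0) = 1,
// monotone increasing, saturates at N for fast lengthening.
double fv_curve(const Model& M, const Muscle& mu, double vce) {
  double vmax = mu.vmax;
  if (vce <= 0) {
    if (vce <= -vmax) return 0.0;
    return (vmax + vce) / (vmax - M.fv_K * vce);
  }
  return M.fv_N - (M.fv_N - 1.0) * vmax / (vmax + 7.56 * M.fv_K * vce);
}

static double fv_inverse(const Model& M, const Muscle& mu, double fv) {
  double vmax = mu.vmax;
  if (fv < 0) fv = 0;
  if (fv < 1.0) {
    return vmax * (fv - 1.0) / (1.0 + M.fv_K * fv);
  }
  double cap = M.fv_N - 1e-3;
  if (fv > cap) fv = cap;
  return vmax * ((M.fv_N - 1.0) / (M.fv_N - fv) - 1.0) / (7.56 * M.fv_K);
}

static double see_force(const Model& M, const Muscle& mu, double lse) {
  double eps = (lse - mu.lslack) / mu.lslack;
  if (eps <= 0) return 0.0;
  double x = eps / M.see_eps_ref;
  return mu.Fmax * x * x;
}

static double pe_force(const Model& M, const Muscle& mu, double lce) {
  if (lce <= mu.lopt) return 0.0;
  double x = (lce - mu.lopt) / (mu.lopt * M.pe_w);
  return mu.Fmax * x * x;
}

void muscle_init(const Model& M, const Muscle& mu, MuscleState& st,
                 double lmtu, double a0) {
  st.a = a0;
  st.lce = lmtu - mu.lslack;          // unstretched tendon
  double lo = 0.4 * mu.lopt, hi = 1.6 * mu.lopt;
  if (st.lce < lo) st.lce = lo;
  if (st.lce > hi) st.lce = hi;
  st.vce = 0;
  st.F = see_force(M, mu, lmtu - st.lce);
}

// One integration step of the contractile dynamics: the CE velocity is the
// one at which CE force (active + parallel-elastic) balances the series
// elastic tendon force; activation follows first-order dynamics toward S.
void muscle_step(const Model& M, const Muscle& mu, MuscleState& st,
                 double S, double lmtu, double dt) {
  if (!std::isfinite(lmtu)) Rcpp::stop("non-finite muscle-tendon length");
  if (S < 0) S = 0; if (S > 1) S = 1;
  double Fse = see_force(M, mu, lmtu - st.lce);
  double fl = fl_curve(M, mu, st.lce);
  double Fpe = pe_force(M, mu, st.lce);
  double denom = st.a * mu.Fmax * fl;
  double fv_req;
  if (denom < 1e-6 * mu.Fmax) denom = 1e-6 * mu.Fmax;
  fv_req = (Fse - Fpe) / denom;
  double vce = fv_inverse(M, mu, fv_req);
  st.lce += vce * dt;
  double lo = 0.3 * mu.lopt, hi = 1.7 * mu.lopt;
  if (st.lce < lo) { st.lce = lo; if (vce < 0) vce = 0; }
  if (st.lce > hi) { st.lce = hi; if (vce > 0) vce = 0; }
  st.vce = vce;
  double tau = (S > st.a) ? mu.tau_act : mu.tau_deact;
  st.a += dt * (S - st.a) / tau;
  if (st.a < 0) st.a = 0; if (st.a > 1) st.a = 1;
  st.F = see_force(M, mu, lmtu - st.lce);
}

} // namespace gp
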