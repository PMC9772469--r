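#include "core.h"

namespace gp {

// Minimize sum F_i^2 subject to R F = tau, 0 <= F (<= ub), by semismooth
// Newton ascent on the concave dual: for multipliers nu the primal minimizer
// is F(nu) = clamp(R' nu / 2, 0, ub), the dual gradient is tau - R F(nu),
// and the generalized Hessian is -R_a R_a'/2 over the strictly-interior
// forces. Armijo backtracking makes the ascent monotone; an unbounded dual
// (torque outside the feasible cone) is reported as infeasible.
arma::vec qp_min_force_bounded(const arma::mat& R, const arma::vec& tau,
                               const arma::vec* ub, bool& feasible,
                               double tol) {
  int k = R.n_cols, m = R.n_rows;
  feasible = true;
  double tnorm = std::max(1.0, arma::norm(tau));
  arma::vec nu(m, arma::fill::zeros);

  auto primal = [&](const arma::vec& v) {
    arma::vec F = R.t() * v / 2.0;
    for (int i = 0; i < k; ++i) {
      if (F(i) < 0) F(i) = 0;
      if (ub && F(i) > (*ub)(i)) F(i) = (*ub)(i);
    }
    return F;
  };
  auto dualval = [&](const arma::vec& v) {
    arma::vec F = primal(v);
    return arma::dot(F, F) - arma::dot(v, R * F - tau);
  };

  arma::vec F = primal(nu);
  double g0 = dualval(nu);
  int it;
  for (it = 0; it < 200; ++it) {
    arma::vec grad = tau - R * F;
    if (arma::norm(grad) <= 1e-12 * tnorm) break;
    // generalized Hessian over strictly interior forces
    arma::mat H(m, m, arma::fill::zeros);
    arma::vec Fu = R.t() * nu / 2.0;
    for (int i = 0; i < k; ++i) {
      bool interior = Fu(i) > 0 && (!ub || Fu(i) < (*ub)(i));
      if (interior) H += R.col(i) * R.col(i).t() / 2.0;
    }
    double reg = 1e-10 * std::max(1.0, arma::trace(H) / m);
    arma::vec d;
    if (!arma::solve(d, H + reg * arma::eye(m, m), grad))
      d = grad; // fall back to steepest ascent
    if (arma::dot(d, grad) <= 0) d = grad;
    // Armijo backtracking on the dual
    double alpha = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 60; ++ls) {
      arma::vec nu_try = nu + alpha * d;
      double g_try = dualval(nu_try);
      if (g_try > g0 + 1e-4 * alpha * arma::dot(grad, d)) {
        nu = nu_try; g0 = g_try; F = primal(nu); moved = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!moved) break;
    if (arma::norm(nu) > 1e14) break; // unbounded dual: infeasible torque
  }
  // polish: exact KKT solve on the converged interior set
  {
    arma::vec Fu = R.t() * nu / 2.0;
    std::vector<int> interior;
    arma::vec rhs = tau;
    for (int i = 0; i < k; ++i) {
      bool in = Fu(i) > 0 && (!ub || Fu(i) < (*ub)(i));
      if (in) interior.push_back(i);
      else if (ub && Fu(i) >= (*ub)(i)) rhs -= R.col(i) * (*ub)(i);
    }
    if (!interior.empty()) {
      arma::mat Ri(m, (int)interior.size());
      for (size_t c = 0; c < interior.size(); ++c) Ri.col(c) = R.col(interior[c]);
      arma::vec y;
      if (arma::solve(y, Ri * Ri.t(), rhs, arma::solve_opts::no_approx)) {
        arma::vec Fi = Ri.t() * y;
        bool okset = true;
        for (size_t c = 0; c < interior.size(); ++c) {
          if (Fi(c) < -1e-9 ||
              (ub && Fi(c) > (*ub)(interior[c]) + 1e-9)) okset = false;
        }
        if (okset) {
          arma::vec Fp(k, arma::fill::zeros);
          for (int i = 0; i < k; ++i)
            if (ub && Fu(i) >= (*ub)(i)) Fp(i) = (*ub)(i);
          for (size_t c = 0; c < interior.size(); ++c)
            Fp(interior[c]) = std::max(0.0, Fi(c));
          if (arma::norm(R * Fp - tau) <= arma::norm(R * F - tau)) F = Fp;
        }
      }
    }
  }
  double resid = arma::norm(R * F - tau);
  if (resid > 1e-6 * tnorm) feasible = false;
  if (!feasible) {
    // least-squares fallback clamped into the box
    arma::vec Fls = arma::pinv(R) * tau;
    for (int i = 0; i < k; ++i) {
      if (Fls(i) < 0) Fls(i) = 0;
      if (ub && Fls(i) > (*ub)(i)) Fls(i) = (*ub)(i);
    }
    return Fls;
  }
  return F;
}

arma::vec qp_min_force(const arma::mat& R, const arma::vec& tau,
                       bool& feasible, double tol) {
  return qp_min_force_bounded(R, tau, nullptr, feasible, tol);
}

} // namespace gp
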