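#include "core.h"

namespace gp {

static arma::mat33 axis_rot(const arma::vec3& a, double th) {
  // Rodrigues formula
  arma::mat33 Kx = {{0, -a(2), a(1)}, {a(2), 0, -a(0)}, {-a(1), a(0), 0}};
  arma::mat33 I; I.eye();
  return I + std::sin(th) * Kx + (1.0 - std::cos(th)) * Kx * Kx;
}

void fk(const Model& M, const arma::vec& q, const arma::vec& qd, Kin& K) {
  size_t n = M.joints.size();
  K.R.resize(n); K.p.resize(n); K.ax.resize(n); K.w.resize(n); K.v.resize(n);
  for (size_t i = 0; i < n; ++i) {
    const Joint& J = M.joints[i];
    arma::mat33 Rp; arma::vec3 pp, wp, vp;
    if (J.parent < 0) { Rp.eye(); pp.zeros(); wp.zeros(); vp.zeros(); }
    else { Rp = K.R[J.parent]; pp = K.p[J.parent]; wp = K.w[J.parent]; vp = K.v[J.parent]; }
    arma::vec3 aw = Rp * J.axis;
    K.ax[i] = aw;
    if (J.type == REVOLUTE) {
      arma::vec3 r = Rp * J.offset;
      K.p[i] = pp + r;
      K.R[i] = Rp * axis_rot(J.axis, q(i));
      K.w[i] = wp + aw * qd(i);
      K.v[i] = vp + arma::cross(wp, r);
    } else {
      arma::vec3 r = Rp * (J.offset + J.axis * q(i));
      K.p[i] = pp + r;
      K.R[i] = Rp;
      K.w[i] = wp;
      K.v[i] = vp + arma::cross(wp, r) + aw * qd(i);
    }
  }
}

// Recursive Newton-Euler in world frame. Returns generalized forces required
// to produce qdd given (q, qd), gravity and optional external wrenches
// (force + torque about the joint origin, world frame, applied per body).
arma::vec rnea(const Model& M, const arma::vec& q, const arma::vec& qd,
               const arma::vec& qdd, bool gravity,
               const std::vector<arma::vec3>* ext_f,
               const std::vector<arma::vec3>* ext_n) {
  size_t n = M.joints.size();
  Kin K; fk(M, q, qd, K);
  std::vector<arma::vec3> wd(n), a(n);        // ang acc, lin acc of joint origin
  arma::vec3 g = {0, 0, gravity ? -M.grav : 0.0};
  for (size_t i = 0; i < n; ++i) {
    const Joint& J = M.joints[i];
    arma::mat33 Rp; arma::vec3 pp, wp, wdp, ap;
    if (J.parent < 0) { Rp.eye(); pp.zeros(); wp.zeros(); wdp.zeros(); ap.zeros(); }
    else { Rp = K.R[J.parent]; pp = K.p[J.parent]; wp = K.w[J.parent];
           wdp = wd[J.parent]; ap = a[J.parent]; }
    arma::vec3 aw = K.ax[i];
    arma::vec3 r = K.p[i] - pp;
    if (J.type == REVOLUTE) {
      wd[i] = wdp + aw * qdd(i) + arma::cross(wp, aw * qd(i));
      a[i] = ap + arma::cross(wdp, r) + arma::cross(wp, arma::cross(wp, r));
    } else {
      wd[i] = wdp;
      a[i] = ap + arma::cross(wdp, r) + arma::cross(wp, arma::cross(wp, r))
           + 2.0 * arma::cross(wp, aw * qd(i)) + aw * qdd(i);
    }
  }
  // backward pass
  std::vector<arma::vec3> Ftot(n), Ntot(n); // net wrench transmitted through joint i
  for (size_t i = 0; i < n; ++i) { Ftot[i].zeros(); Ntot[i].zeros(); }
  arma::vec tau(n, arma::fill::zeros);
  for (int i = (int)n - 1; i >= 0; --i) {
    const Joint& J = M.joints[i];
    arma::vec3 Fi(arma::fill::zeros), Ni(arma::fill::zeros);
    if (J.m > 0) {
      arma::vec3 cw = K.R[i] * J.com;            // com rel joint origin, world
      arma::vec3 ci = K.p[i] + cw;
      arma::vec3 ac = a[i] + arma::cross(wd[i], cw)
                    + arma::cross(K.w[i], arma::cross(K.w[i], cw));
      arma::mat33 Iw = K.R[i] * J.I * K.R[i].t();
      Fi = J.m * (ac - g);
      Ni = Iw * wd[i] + arma::cross(K.w[i], Iw * K.w[i]) + arma::cross(cw, Fi);
      (void)ci;
    }
    if (ext_f) { Fi -= (*ext_f)[i]; Ni -= (*ext_n)[i]; }
    Ftot[i] += Fi; Ntot[i] += Ni;
    if (J.parent >= 0) {
      Ftot[J.parent] += Ftot[i];
      Ntot[J.parent] += Ntot[i] + arma::cross(K.p[i] - K.p[J.parent], Ftot[i]);
    }
    tau(i) = (J.type == REVOLUTE) ? arma::dot(K.ax[i], Ntot[i])
                                  : arma::dot(K.ax[i], Ftot[i]);
  }
  return tau;
}

// Composite-rigid-body mass matrix in world frame (single backward pass);
// used by the inner simulation loop. mass_matrix() below assembles M by
// unit-acceleration inverse dynamics and serves as the reference.
arma::mat crba(const Model& M, const Kin& K) {
  size_t n = M.joints.size();
  arma::mat Mm(n, n, arma::fill::zeros);
  std::vector<double> mc(n);
  std::vector<arma::vec3> cc(n);
  std::vector<arma::mat33> Ic(n);
  for (size_t i = 0; i < n; ++i) {
    mc[i] = M.joints[i].m;
    cc[i] = (mc[i] > 0) ? arma::vec3(K.p[i] + K.R[i] * M.joints[i].com)
                        : arma::vec3(arma::fill::zeros);
    Ic[i] = (mc[i] > 0) ? arma::mat33(K.R[i] * M.joints[i].I * K.R[i].t())
                        : arma::mat33(arma::fill::zeros);
  }
  arma::mat33 E; E.eye();
  for (int i = (int)n - 1; i >= 0; --i) {
    int par = M.joints[i].parent;
    if (par >= 0 && mc[i] > 0) {
      double m_new = mc[par] + mc[i];
      arma::vec3 c_new = (mc[par] * cc[par] + mc[i] * cc[i]) / m_new;
      arma::mat33 I_new(arma::fill::zeros);
      if (mc[par] > 0) {
        arma::vec3 d = cc[par] - c_new;
        I_new += Ic[par] + mc[par] * (arma::dot(d, d) * E - d * d.t());
      }
      arma::vec3 d = cc[i] - c_new;
      I_new += Ic[i] + mc[i] * (arma::dot(d, d) * E - d * d.t());
      mc[par] = m_new; cc[par] = c_new; Ic[par] = I_new;
    }
    if (mc[i] <= 0) continue;
    // unit-acceleration wrench of joint i on its composite subtree
    arma::vec3 f, nn;
    if (M.joints[i].type == REVOLUTE) {
      arma::vec3 d = cc[i] - K.p[i];
      f = mc[i] * arma::cross(K.ax[i], d);
      nn = Ic[i] * K.ax[i] + mc[i] * arma::cross(d, arma::cross(K.ax[i], d));
    } else {
      f = mc[i] * K.ax[i];
      nn = arma::cross(cc[i] - K.p[i], f);
    }
    // project onto joint i and all its ancestors
    int j = i;
    while (j >= 0) {
      double mij;
      if (M.joints[j].type == REVOLUTE) {
        arma::vec3 nj = nn + arma::cross(K.p[i] - K.p[j], f);
        mij = arma::dot(K.ax[j], nj);
      } else {
        mij = arma::dot(K.ax[j], f);
      }
      Mm(j, i) = mij; Mm(i, j) = mij;
      j = M.joints[j].parent;
    }
  }
  return Mm;
}

arma::mat mass_matrix(const Model& M, const arma::vec& q) {
  size_t n = M.joints.size();
  arma::vec zero(n, arma::fill::zeros);
  arma::mat Mm(n, n);
  for (size_t j = 0; j < n; ++j) {
    arma::vec ej(n, arma::fill::zeros); ej(j) = 1.0;
    Mm.col(j) = rnea(M, q, zero, ej, false);
  }
  return 0.5 * (Mm + Mm.t());
}

void contact_forces(const Model& M, const Kin& K, const arma::vec& q,
                    const arma::vec& qd,
                    std::vector<arma::vec3>& ext_f, std::vector<arma::vec3>& ext_n,
                    arma::mat& per_sphere, double& cop_x, double& cop_y,
                    double fz_tot[2]) {
  size_t n = M.joints.size();
  ext_f.assign(n, arma::vec3(arma::fill::zeros));
  ext_n.assign(n, arma::vec3(arma::fill::zeros));
  size_t ns = M.spheres.size();
  per_sphere.set_size(ns, 8); per_sphere.zeros(); // fx fy fz flag pen cx cy cz
  double wsum = 0, wx = 0, wy = 0;
  fz_tot[0] = fz_tot[1] = 0;
  for (size_t s = 0; s < ns; ++s) {
    const Sphere& S = M.spheres[s];
    int j = S.joint;
    arma::vec3 cw = K.R[j] * S.pos;
    arma::vec3 c = K.p[j] + cw;
    double pen = S.radius - c(2);
    per_sphere(s, 5) = c(0); per_sphere(s, 6) = c(1); per_sphere(s, 7) = c(2);
    if (pen <= 0) continue;
    per_sphere(s, 3) = 1; per_sphere(s, 4) = pen;
    arma::vec3 vc = K.v[j] + arma::cross(K.w[j], cw);
    double pend = -vc(2);
    double fn = M.k_contact * pen * (1.0 + M.c_contact * pend);
    if (fn < 0) fn = 0;
    double vt = std::sqrt(vc(0) * vc(0) + vc(1) * vc(1));
    arma::vec3 f = {0, 0, fn};
    if (vt > 1e-12) {
      double ft = M.mu_fric * fn * std::tanh(vt / M.v_reg);
      f(0) = -ft * vc(0) / vt;
      f(1) = -ft * vc(1) / vt;
    }
    per_sphere(s, 0) = f(0); per_sphere(s, 1) = f(1); per_sphere(s, 2) = f(2);
    ext_f[j] += f;
    ext_n[j] += arma::cross(c - K.p[j], f);
    wsum += fn; wx += fn * c(0); wy += fn * c(1);
    fz_tot[(j == M.j_ankle[0]) ? 0 : 1] += fn;
  }
  if (wsum > 1e-9) { cop_x = wx / wsum; cop_y = wy / wsum; }
  else { cop_x = NA_REAL; cop_y = NA_REAL; }
}

arma::vec forward_dynamics(const Model& M, const arma::vec& q, const arma::vec& qd,
                           const arma::vec& tau8, bool with_contact) {
  size_t n = M.joints.size();
  arma::vec Q(n, arma::fill::zeros);
  for (size_t i = 6; i < n; ++i) Q(i) = tau8(i - 6);
  std::vector<arma::vec3> ef, en;
  arma::vec bias;
  if (with_contact) {
    Kin K; fk(M, q, qd, K);
    arma::mat ps; double cx, cy; double fz[2];
    contact_forces(M, K, q, qd, ef, en, ps, cx, cy, fz);
    bias = rnea(M, q, qd, arma::vec(n, arma::fill::zeros), true, &ef, &en);
  } else {
    bias = rnea(M, q, qd, arma::vec(n, arma::fill::zeros), true);
  }
  arma::mat Mm = mass_matrix(M, q);
  return arma::solve(Mm, Q - bias, arma::solve_opts::likely_sympd);
}

double energy(const Model& M, const arma::vec& q, const arma::vec& qd) {
  Kin K; fk(M, q, qd, K);
  double E = 0;
  for (size_t i = 0; i < M.joints.size(); ++i) {
    const Joint& J = M.joints[i];
    if (J.m <= 0) continue;
    arma::vec3 cw = K.R[i] * J.com;
    arma::vec3 vc = K.v[i] + arma::cross(K.w[i], cw);
    arma::mat33 Iw = K.R[i] * J.I * K.R[i].t();
    E += 0.5 * J.m * arma::dot(vc, vc) + 0.5 * arma::dot(K.w[i], Iw * K.w[i]);
    E += J.m * M.grav * (K.p[i](2) + cw(2));
  }
  return E;
}

arma::vec3 total_com(const Model& M, const Kin& K, double& mass_out) {
  arma::vec3 c(arma::fill::zeros); double m = 0;
  for (size_t i = 0; i < M.joints.size(); ++i) {
    const Joint& J = M.joints[i];
    if (J.m <= 0) continue;
    c += J.m * (K.p[i] + K.R[i] * J.com);
    m += J.m;
  }
  mass_out = m;
  return c / m;
}

// Stance-chain Jacobian (6x5) and mass matrix (5x5).
// Chain runs ground-up: ball hinge, ankle, knee, hip flexion, hip abduction,
// with the stance foot held fixed; output column/row order is
// (hipfl, hipab, knee, ankle, ball) to match the planner contract.
void chain_jacobian_mass(const Model& M, const Kin& K, int side,
                         const arma::vec3& p_ball, arma::mat& J, arma::mat& Mc,
                         bool composite_trunk) {
  int jab = M.j_hipab[side], jfl = M.j_hipfl[side],
      jkn = M.j_knee[side], jan = M.j_ankle[side];
  int jtr = M.j_trunk;
  // trunk CoM (trunk body only, per the task definition)
  arma::vec3 c_tr = K.p[jtr] + K.R[jtr] * M.joints[jtr].com;

  // inverted-chain world axes: proximal part rotates by -axis when the joint
  // angle (distal-re-proximal convention) increases
  arma::vec3 s_ball = K.R[jan] * arma::vec3({0, 1, 0});
  arma::vec3 s[5];      // ground-up: ball, ankle, knee, hipfl, hipab
  arma::vec3 pj[5];
  s[0] = s_ball;              pj[0] = p_ball;
  s[1] = -K.ax[jan];          pj[1] = K.p[jan];
  s[2] = -K.ax[jkn];          pj[2] = K.p[jkn];
  s[3] = -K.ax[jfl];          pj[3] = K.p[jfl];
  s[4] = -K.ax[jab];          pj[4] = K.p[jab];

  // J: trunk CoM twist per unit joint rate; output order hipfl,hipab,knee,ankle,ball
  int omap[5] = {3, 4, 2, 1, 0}; // output col k comes from ground-up index omap[k]
  J.set_size(6, 5);
  for (int k = 0; k < 5; ++k) {
    int i = omap[k];
    arma::vec3 vcol = arma::cross(s[i], c_tr - pj[i]);
    J(0, k) = vcol(0); J(1, k) = vcol(1); J(2, k) = vcol(2);
    J(3, k) = s[i](0); J(4, k) = s[i](1); J(5, k) = s[i](2);
  }

  // bodies carried above each ground-up joint:
  //   ball -> foot, ankle -> shank, knee -> thigh, hipfl -> none,
  //   hipab -> nothing (leg-only chain inertia, the mass-matrix block used
  //   by the internal model) or the trunk + swing-leg composite (frozen at
  //   the current configuration) when composite_trunk is set
  double mb[5]; arma::vec3 cb[5]; arma::mat33 Ib[5];
  auto body_world = [&](int j, double& m, arma::vec3& c, arma::mat33& I) {
    const Joint& B = M.joints[j];
    m = B.m; c = K.p[j] + K.R[j] * B.com; I = K.R[j] * B.I * K.R[j].t();
  };
  body_world(jan, mb[0], cb[0], Ib[0]);   // foot
  body_world(jkn, mb[1], cb[1], Ib[1]);   // shank
  body_world(jfl, mb[2], cb[2], Ib[2]);   // thigh
  mb[3] = 0; cb[3].zeros(); Ib[3].zeros();
  mb[4] = 0; cb[4].zeros(); Ib[4].zeros();
  if (composite_trunk) {
    int other = 1 - side;
    int idx[4] = {jtr, M.j_hipfl[other], M.j_knee[other], M.j_ankle[other]};
    double mc = 0; arma::vec3 cc(arma::fill::zeros);
    for (int t = 0; t < 4; ++t) {
      const Joint& B = M.joints[idx[t]];
      mc += B.m; cc += B.m * (K.p[idx[t]] + K.R[idx[t]] * B.com);
    }
    cc /= mc;
    arma::mat33 Ic(arma::fill::zeros);
    for (int t = 0; t < 4; ++t) {
      const Joint& B = M.joints[idx[t]];
      arma::vec3 d = (K.p[idx[t]] + K.R[idx[t]] * B.com) - cc;
      arma::mat33 Iw = K.R[idx[t]] * B.I * K.R[idx[t]].t();
      arma::mat33 dd = d * d.t();
      arma::mat33 E; E.eye();
      Ic += Iw + B.m * (arma::dot(d, d) * E - dd);
    }
    mb[4] = mc; cb[4] = cc; Ib[4] = Ic;
  }

  // serial composite-rigid-body assembly, ground-up
  arma::mat Mg(5, 5, arma::fill::zeros);
  double m_comp = 0; arma::vec3 c_comp(arma::fill::zeros);
  arma::mat33 I_comp(arma::fill::zeros);
  for (int k = 4; k >= 0; --k) {
    // add body k into the composite (inertia about the composite CoM)
    double m_new = m_comp + mb[k];
    if (m_new > 0) {
      arma::vec3 c_new = (m_comp * c_comp + mb[k] * cb[k]) / m_new;
      arma::mat33 E; E.eye();
      arma::mat33 I_new(arma::fill::zeros);
      if (m_comp > 0) {
        arma::vec3 d = c_comp - c_new;
        I_new += I_comp + m_comp * (arma::dot(d, d) * E - d * d.t());
      }
      if (mb[k] > 0) {
        arma::vec3 d = cb[k] - c_new;
        I_new += Ib[k] + mb[k] * (arma::dot(d, d) * E - d * d.t());
      }
      m_comp = m_new; c_comp = c_new; I_comp = I_new;
    }
    if (m_comp <= 0) continue;
    // unit acceleration of ground-up joint k acting on composite above it
    arma::vec3 dk = c_comp - pj[k];
    arma::vec3 f = m_comp * arma::cross(s[k], dk);
    arma::vec3 nk = I_comp * s[k] + m_comp * arma::cross(dk, arma::cross(s[k], dk));
    for (int i = 0; i <= k; ++i) {
      arma::vec3 ni = nk + arma::cross(pj[k] - pj[i], f);
      Mg(i, k) = arma::dot(s[i], ni);
      Mg(k, i) = Mg(i, k);
    }
  }
  Mc.set_size(5, 5);
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      Mc(a, b) = Mg(omap[a], omap[b]);
}

// Inverse dynamics of the 4-joint swing chain (hip abduction, hip flexion,
// knee, ankle) treating the pelvis as a moving base: the chain inherits the
// trunk's angular velocity, gravity is included, base linear acceleration is
// neglected. qdd_des order: (hipfl, hipab, knee, ankle); returned the same.
arma::vec swing_inverse_dynamics(const Model& M, const arma::vec& q,
                                 const arma::vec& qd, int side,
                                 const arma::vec& qdd_des, bool base_motion) {
  Kin K; fk(M, q, qd, K);
  int ch[4] = {M.j_hipab[side], M.j_hipfl[side], M.j_knee[side], M.j_ankle[side]};
  arma::vec3 g = {0, 0, -M.grav};
  // base (trunk) state
  int jtr = M.j_trunk;
  arma::vec3 w0 = base_motion ? K.w[jtr] : arma::vec3(arma::fill::zeros);
  // chain order: hipab, hipfl, knee, ankle; map desired accelerations
  double qdd[4] = {qdd_des(1), qdd_des(0), qdd_des(2), qdd_des(3)};
  arma::vec3 w[4], wd[4], a[4];
  for (int i = 0; i < 4; ++i) {
    int j = ch[i];
    arma::vec3 wp = (i == 0) ? w0 : w[i - 1];
    arma::vec3 wdp = (i == 0) ? arma::vec3(arma::fill::zeros) : wd[i - 1];
    arma::vec3 ap = (i == 0) ? arma::vec3(arma::fill::zeros) : a[i - 1];
    arma::vec3 pp = (i == 0) ? K.p[jtr] : K.p[ch[i - 1]];
    arma::vec3 r = K.p[j] - pp;
    double qdj = qd(j);
    w[i] = wp + K.ax[j] * qdj;
    wd[i] = wdp + K.ax[j] * qdd[i] + arma::cross(wp, K.ax[j] * qdj);
    a[i] = ap + arma::cross(wdp, r) + arma::cross(wp, arma::cross(wp, r));
  }
  arma::vec3 Ftot[4], Ntot[4];
  for (int i = 0; i < 4; ++i) { Ftot[i].zeros(); Ntot[i].zeros(); }
  arma::vec tau_ch(4, arma::fill::zeros);
  for (int i = 3; i >= 0; --i) {
    int j = ch[i];
    const Joint& B = M.joints[j];
    arma::vec3 Fi(arma::fill::zeros), Ni(arma::fill::zeros);
    if (B.m > 0) {
      arma::vec3 cw = K.R[j] * B.com;
      arma::vec3 ac = a[i] + arma::cross(wd[i], cw)
                    + arma::cross(w[i], arma::cross(w[i], cw));
      arma::mat33 Iw = K.R[j] * B.I * K.R[j].t();
      Fi = B.m * (ac - g);
      Ni = Iw * wd[i] + arma::cross(w[i], Iw * w[i]) + arma::cross(cw, Fi);
    }
    Ftot[i] += Fi; Ntot[i] += Ni;
    if (i > 0) {
      Ftot[i - 1] += Ftot[i];
      Ntot[i - 1] += Ntot[i] + arma::cross(K.p[j] - K.p[ch[i - 1]], Ftot[i]);
    }
    tau_ch(i) = arma::dot(K.ax[j], Ntot[i]);
  }
  // reorder chain (hipab, hipfl, knee, ankle) -> (hipfl, hipab, knee, ankle)
  return arma::vec({tau_ch(1), tau_ch(0), tau_ch(2), tau_ch(3)});
}

} // namespace gp
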