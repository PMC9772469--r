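#include "core.h"

namespace gp {

static arma::vec3 v3(const Rcpp::NumericVector& v) {
  return arma::vec3({v[0], v[1], v[2]});
}

static arma::mat33 diag3(const Rcpp::NumericVector& v) {
  arma::mat33 I(arma::fill::zeros);
  I(0, 0) = v[0]; I(1, 1) = v[1]; I(2, 2) = v[2];
  return I;
}

static int joint_index(const std::string& nm, int leg) {
  // leg 0 left -> joints 6..9, leg 1 right -> 10..13
  int base = (leg == 0) ? 6 : 10;
  if (nm == "hipab") return base + 0;
  if (nm == "hipfl") return base + 1;
  if (nm == "knee") return base + 2;
  if (nm == "ankle") return base + 3;
  Rcpp::stop("unknown joint name: " + nm);
}

Model build_model(const Rcpp::List& cfg) {
  Model M;
  M.grav = Rcpp::as<double>(cfg["gravity"]);
  Rcpp::List con = cfg["contact"];
  M.k_contact = Rcpp::as<double>(con["k"]);
  M.c_contact = Rcpp::as<double>(con["c"]);
  M.mu_fric = Rcpp::as<double>(con["mu"]);
  M.v_reg = Rcpp::as<double>(con["v_reg"]);

  Rcpp::List hill = cfg["hill"];
  M.fl_w = Rcpp::as<double>(hill["fl_w"]);
  M.fl_c = Rcpp::as<double>(hill["fl_c"]);
  M.fv_K = Rcpp::as<double>(hill["fv_K"]);
  M.fv_N = Rcpp::as<double>(hill["fv_N"]);
  M.see_eps_ref = Rcpp::as<double>(hill["see_eps_ref"]);
  M.pe_w = Rcpp::as<double>(hill["pe_w"]);
  M.stim_floor = Rcpp::as<double>(hill["stim_floor"]);

  Rcpp::List trunk = cfg["trunk"], thigh = cfg["thigh"],
             shank = cfg["shank"], foot = cfg["foot"];
  double hip_y = Rcpp::as<double>(trunk["hip_offset_y"]);
  double L_th = Rcpp::as<double>(thigh["length"]);
  double L_sh = Rcpp::as<double>(shank["length"]);
  M.ball_x = Rcpp::as<double>(foot["ball_x"]);
  M.sole_z = Rcpp::as<double>(foot["sole_z"]);

  auto J0 = [](int parent, int type, arma::vec3 axis, arma::vec3 off) {
    Joint j; j.parent = parent; j.type = type; j.axis = axis; j.offset = off;
    j.m = 0; j.com.zeros(); j.I.zeros(); return j;
  };
  arma::vec3 z3(arma::fill::zeros);
  M.joints.clear();
  M.joints.push_back(J0(-1, PRISMATIC, {1, 0, 0}, z3));
  M.joints.push_back(J0(0, PRISMATIC, {0, 1, 0}, z3));
  M.joints.push_back(J0(1, PRISMATIC, {0, 0, 1}, z3));
  M.joints.push_back(J0(2, REVOLUTE, {0, 0, 1}, z3));
  M.joints.push_back(J0(3, REVOLUTE, {0, 1, 0}, z3));
  Joint tr = J0(4, REVOLUTE, {1, 0, 0}, z3);
  tr.m = Rcpp::as<double>(trunk["mass"]);
  tr.com = v3(trunk["com"]); tr.I = diag3(trunk["inertia"]);
  M.joints.push_back(tr);
  for (int leg = 0; leg < 2; ++leg) {
    double sy = (leg == 0) ? 1.0 : -1.0;
    Joint hab = J0(5, REVOLUTE, {sy, 0, 0}, {0, sy * hip_y, 0});
    M.joints.push_back(hab);
    Joint hfl = J0((int)M.joints.size() - 1, REVOLUTE, {0, -1, 0}, z3);
    hfl.m = Rcpp::as<double>(thigh["mass"]);
    hfl.com = v3(thigh["com"]); hfl.I = diag3(thigh["inertia"]);
    M.joints.push_back(hfl);
    Joint kne = J0((int)M.joints.size() - 1, REVOLUTE, {0, 1, 0}, {0, 0, -L_th});
    kne.m = Rcpp::as<double>(shank["mass"]);
    kne.com = v3(shank["com"]); kne.I = diag3(shank["inertia"]);
    M.joints.push_back(kne);
    Joint ank = J0((int)M.joints.size() - 1, REVOLUTE, {0, -1, 0}, {0, 0, -L_sh});
    ank.m = Rcpp::as<double>(foot["mass"]);
    arma::vec3 fc = v3(foot["com"]); fc(1) *= sy;
    ank.com = fc; ank.I = diag3(foot["inertia"]);
    M.joints.push_back(ank);
    M.j_hipab[leg] = 6 + 4 * leg; M.j_hipfl[leg] = 7 + 4 * leg;
    M.j_knee[leg] = 8 + 4 * leg; M.j_ankle[leg] = 9 + 4 * leg;
  }
  M.j_trunk = 5;

  Rcpp::List jl = cfg["joints"];
  M.joint_damping = Rcpp::as<double>(jl["damping"]);
  M.k_limit = Rcpp::as<double>(jl["k_limit"]);
  M.d_limit = Rcpp::as<double>(jl["d_limit"]);
  Rcpp::List lim = jl["limits"];
  for (int i = 0; i < 14; ++i) { M.qmin[i] = -1e9; M.qmax[i] = 1e9; }
  const char* lnames[4] = {"hipab", "hipfl", "knee", "ankle"};
  for (int leg = 0; leg < 2; ++leg) {
    int idx[4] = {M.j_hipab[leg], M.j_hipfl[leg], M.j_knee[leg], M.j_ankle[leg]};
    for (int k = 0; k < 4; ++k) {
      Rcpp::NumericVector lv = lim[lnames[k]];
      M.qmin[idx[k]] = lv[0]; M.qmax[idx[k]] = lv[1];
    }
  }

  Rcpp::List sph = foot["spheres"];
  M.spheres.clear();
  for (int leg = 0; leg < 2; ++leg) {
    double sy = (leg == 0) ? 1.0 : -1.0;
    for (int s = 0; s < sph.size(); ++s) {
      Rcpp::List si = sph[s];
      Sphere sp;
      sp.joint = M.j_ankle[leg];
      arma::vec3 pos = v3(si["pos"]); pos(1) *= sy;
      sp.pos = pos;
      sp.radius = Rcpp::as<double>(si["radius"]);
      M.spheres.push_back(sp);
    }
  }

  Rcpp::List mus = cfg["muscles"];
  M.muscles.clear();
  for (int leg = 0; leg < 2; ++leg) {
    for (int m = 0; m < mus.size(); ++m) {
      Rcpp::List mi = mus[m];
      Muscle mm;
      mm.name = Rcpp::as<std::string>(mi["name"]);
      mm.leg = leg;
      mm.Fmax = Rcpp::as<double>(mi["fmax"]);
      mm.lopt = Rcpp::as<double>(mi["lopt"]);
      mm.lslack = Rcpp::as<double>(mi["lslack"]);
      mm.vmax = Rcpp::as<double>(mi["vmax_rel"]) * mm.lopt;
      mm.tau_act = Rcpp::as<double>(mi["tau_act"]);
      mm.tau_deact = Rcpp::as<double>(mi["tau_deact"]);
      mm.delay_s = Rcpp::as<double>(mi["delay"]);
      Rcpp::List arms = mi["arms"];
      for (int a = 0; a < arms.size(); ++a) {
        Rcpp::List ai = arms[a];
        ArmSpec as_;
        as_.qidx = joint_index(Rcpp::as<std::string>(ai["joint"]), leg);
        as_.type = (Rcpp::as<std::string>(ai["type"]) == "cos") ? 1 : 0;
        as_.r0 = Rcpp::as<double>(ai["r0"]);
        as_.th_max = Rcpp::as<double>(ai["th_max"]);
        as_.th_ref = Rcpp::as<double>(ai["th_ref"]);
        mm.arms.push_back(as_);
      }
      M.muscles.push_back(mm);
    }
  }

  // reference standing trunk CoM height (legs straight, soles on the ground)
  double z0 = -M.sole_z + L_sh + L_th;
  arma::vec q0(14, arma::fill::zeros); q0(2) = z0;
  Kin K; arma::vec qd0(14, arma::fill::zeros);
  fk(M, q0, qd0, K);
  arma::vec3 trunk_com_w = K.R[5] * M.joints[5].com;
  M.standing_z = K.p[5](2) + trunk_com_w(2);
  return M;
}

} // namespace gp
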