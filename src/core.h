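#ifndef GAITPLANR_CORE_H
#define GAITPLANR_CORE_H

#include <RcppArmadillo.h>
#include <vector>
#include <string>

// Rigid-body tree of the walker. 14 single-DoF joints: the 6 free-body
// coordinates of the trunk are chained prismatic (x,y,z) and revolute
// (yaw-z, pitch-y, roll-x) joints with massless links; each leg adds
// hip abduction (x), hip flexion (-y), knee flexion (+y), ankle
// dorsiflexion (-y). Forward = +x, left = +y, up = +z.

namespace gp {

enum JointType { PRISMATIC = 0, REVOLUTE = 1 };

struct Joint {
  int parent;            // -1 for root
  int type;              // PRISMATIC / REVOLUTE
  arma::vec3 axis;       // in parent frame
  arma::vec3 offset;     // joint origin in parent joint frame
  double m;              // mass of attached body (0 for virtual links)
  arma::vec3 com;        // body CoM in this joint frame
  arma::mat33 I;         // inertia about CoM, in this joint frame
};

struct ArmSpec {
  int qidx;              // generalized coordinate index (6..13)
  int type;              // 0 constant, 1 cosine-modulated
  double r0;             // signed arm, + = positive joint torque
  double th_max;         // angle of maximal arm (cosine type)
  double th_ref;         // reference angle where this joint adds no length
};

struct Muscle {
  std::string name;
  int leg;               // 0 left, 1 right
  double Fmax, lopt, lslack, vmax; // vmax in m/s (lengthening positive)
  double tau_act, tau_deact;
  std::vector<ArmSpec> arms;
  double delay_s;        // proprioceptive delay in seconds
};

struct Sphere {
  int joint;             // foot joint index (9 left, 13 right)
  arma::vec3 pos;        // centre in foot frame
  double radius;
};

struct Model {
  std::vector<Joint> joints;        // 14
  std::vector<Sphere> spheres;      // 8
  std::vector<Muscle> muscles;      // 20
  double grav;                      // 9.81
  double k_contact, c_contact, mu_fric, v_reg;
  double ball_x, sole_z;            // ball-of-foot hinge point in foot frame
  // anatomical joint limits (soft stops) and joint damping, indices 6..13
  double qmin[14], qmax[14], k_limit, d_limit, joint_damping;
  // Hill characteristics (shared shape constants)
  double fl_w, fl_c, fv_K, fv_N, see_eps_ref, pe_w;
  double stim_floor;
  // convenience index maps [left, right]
  int j_hipab[2], j_hipfl[2], j_knee[2], j_ankle[2], j_trunk;
  double standing_z;                // trunk CoM height at reference posture
};

struct Kin {
  std::vector<arma::mat33> R;   // world rotation of joint frame
  std::vector<arma::vec3> p;    // world position of joint origin
  std::vector<arma::vec3> ax;   // world joint axis
  std::vector<arma::vec3> w;    // world angular velocity of link
  std::vector<arma::vec3> v;    // world linear velocity of joint origin
};

// --- dynamics.cpp ---
void fk(const Model& M, const arma::vec& q, const arma::vec& qd, Kin& K);
arma::vec rnea(const Model& M, const arma::vec& q, const arma::vec& qd,
               const arma::vec& qdd, bool gravity,
               const std::vector<arma::vec3>* ext_f = nullptr,
               const std::vector<arma::vec3>* ext_n = nullptr);
arma::mat mass_matrix(const Model& M, const arma::vec& q);
arma::mat crba(const Model& M, const Kin& K);
void contact_forces(const Model& M, const Kin& K, const arma::vec& q,
                    const arma::vec& qd,
                    std::vector<arma::vec3>& ext_f, std::vector<arma::vec3>& ext_n,
                    arma::mat& per_sphere, double& cop_x, double& cop_y,
                    double fz_tot[2]);
arma::vec forward_dynamics(const Model& M, const arma::vec& q, const arma::vec& qd,
                           const arma::vec& tau8, bool with_contact);
double energy(const Model& M, const arma::vec& q, const arma::vec& qd);
arma::vec3 total_com(const Model& M, const Kin& K, double& mass_out);

// stance-chain quantities (order: hipfl, hipab, knee, ankle, ball)
void chain_jacobian_mass(const Model& M, const Kin& K, int side,
                         const arma::vec3& p_ball, arma::mat& J, arma::mat& Mc,
                         bool composite_trunk = false);
arma::vec swing_inverse_dynamics(const Model& M, const arma::vec& q,
                                 const arma::vec& qd, int side,
                                 const arma::vec& qdd_des,
                                 bool base_motion);

// muscle.cpp
struct MuscleState { double a, lce, vce, F; };
double muscle_lmtu(const Model& M, const Muscle& mu, const arma::vec& q);
void muscle_arms(const Model& M, const Muscle& mu, const arma::vec& q,
                 std::vector<std::pair<int,double>>& out);
double fl_curve(const Model& M, const Muscle& mu, double lce);
double fv_curve(const Model& M, const Muscle& mu, double vce);
void muscle_step(const Model& M, const Muscle& mu, MuscleState& st,
                 double S, double lmtu, double dt);
void muscle_init(const Model& M, const Muscle& mu, MuscleState& st,
                 double lmtu, double a0);

// qp.cpp
arma::vec qp_min_force(const arma::mat& R, const arma::vec& tau,
                       bool& feasible, double tol = 1e-10);
arma::vec qp_min_force_bounded(const arma::mat& R, const arma::vec& tau,
                               const arma::vec* ub, bool& feasible,
                               double tol = 1e-10);

Model build_model(const Rcpp::List& cfg);

} // namespace gp

#endif
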