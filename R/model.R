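#' Load the skeletal and muscular model
#'
#' Reads a structured model description (segments, joints, contact spheres,
#' muscle routing and Hill constants) and assembles the rigid-body tree used
#' by the simulator. The walker has 14 degrees of freedom: six free-body
#' coordinates of the trunk (x, y, z, yaw, pitch, roll) followed by hip
#' abduction, hip flexion, knee flexion and ankle dorsiflexion for the left
#' then the right leg. Forward is +x, left +y, up +z; angles are in radians.
#'
#' @param path Path to a YAML model description. `NULL` loads the default
#'   model shipped with the package (1.80 m / 80 kg adult, 10 muscles per
#'   leg).
#' @return An object of class `walker_model`.
#' @examples
#' model <- load_model()
#' model
#' @export
load_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_model.yaml", package = "gaitplanr")
  }
  cfg <- yaml::read_yaml(path)
  new_walker_model(cfg, path)
}

new_walker_model <- function(cfg, path = NA_character_) {
  ptr <- wk_build_model(cfg)
  info <- wk_model_info(ptr)
  z0 <- -cfg$foot$sole_z + cfg$shank$length + cfg$thigh$length
  q0 <- numeric(14)
  q0[3] <- z0
  structure(
    list(cfg = cfg, ptr = ptr, info = info, q0 = q0, path = path),
    class = "walker_model"
  )
}

# XPtr objects do not survive serialization; rebuild transparently.
model_ptr <- function(model) {
  stopifnot(inherits(model, "walker_model"))
  p <- model$ptr
  if (is.null(p) || identical(utils::capture.output(p), "<pointer: 0x0>")) {
    p <- wk_build_model(model$cfg)
  }
  p
}

#' @export
print.walker_model <- function(x, ...) {
  cat("<walker_model>\n")
  cat(sprintf("  DoF: %d  total mass: %.1f kg  standing trunk CoM: %.3f m\n",
              x$info$n_dof, x$info$total_mass, x$info$standing_z))
  cat(sprintf("  muscles: %d (%d per leg)  contact spheres: %d\n",
              length(x$info$muscle_names), sum(x$info$muscle_leg == 0),
              x$info$n_spheres))
  invisible(x)
}

#' Names of the generalized coordinates
#'
#' @return Character vector of length 14 in coordinate order.
#' @export
coordinate_names <- function() {
  c("x", "y", "z", "yaw", "pitch", "roll",
    "hipab_l", "hipfl_l", "knee_l", "ankle_l",
    "hipab_r", "hipfl_r", "knee_r", "ankle_r")
}

#' Names of the actuated joints (torque vector order)
#' @return Character vector of length 8.
#' @export
joint_names <- function() coordinate_names()[7:14]

#' Muscle names for one leg
#' @param model A `walker_model`.
#' @return Character vector (default model: 10 muscles).
#' @export
muscle_names <- function(model = load_model()) {
  as.character(model$info$muscle_names[model$info$muscle_leg == 0])
}

#' Neutral standing state
#'
#' Generalized coordinates of the reference posture: straight legs, trunk
#' upright, soles level with the ground.
#'
#' @param model A `walker_model`.
#' @param v_x Initial forward speed in m/s.
#' @return A list with elements `q` and `qd` (length-14 numeric vectors).
#' @export
standing_state <- function(model, v_x = 0) {
  qd <- numeric(14)
  qd[1] <- v_x
  list(q = model$q0, qd = qd)
}

#' Forward dynamics of the walker
#'
#' Solves the articulated equation of motion
#' \eqn{M(q)\ddot q + b(q,\dot q) = Q} for the generalized accelerations,
#' optionally including ground contact forces.
#'
#' @param model A `walker_model`.
#' @param state List with numeric vectors `q` and `qd` (length 14).
#' @param joint_torques Torques for the 8 actuated joints (N m), in
#'   [joint_names()] order.
#' @param contact Include ground contact forces (default `TRUE`).
#' @return Numeric vector of 14 generalized accelerations.
#' @export
forward_dynamics <- function(model, state, joint_torques = numeric(8),
                             contact = TRUE) {
  stopifnot(length(state$q) == 14, length(state$qd) == 14,
            length(joint_torques) == 8)
  if (!all(is.finite(c(state$q, state$qd, joint_torques)))) {
    stop("non-finite state or torque input")
  }
  as.numeric(wk_forward_dynamics(model_ptr(model), state$q, state$qd,
                                 joint_torques, contact))
}

#' Joint-space mass matrix
#'
#' @param model A `walker_model`.
#' @param q Generalized coordinates (length 14).
#' @return Symmetric positive-definite 14 x 14 matrix.
#' @export
mass_matrix <- function(model, q) {
  m <- wk_mass_matrix(model_ptr(model), q)
  dimnames(m) <- list(coordinate_names(), coordinate_names())
  m
}

#' Generalized forces by recursive Newton-Euler
#'
#' Returns the generalized forces required to produce accelerations `qdd`
#' at state (`q`, `qd`), optionally including gravity. Used for inverse
#' dynamics and for assembling the equation of motion in tests.
#'
#' @param model A `walker_model`.
#' @param q,qd,qdd Numeric vectors of length 14.
#' @param gravity Include gravity (default `TRUE`).
#' @return Numeric vector of 14 generalized forces.
#' @export
inverse_dynamics_full <- function(model, q, qd, qdd, gravity = TRUE) {
  as.numeric(wk_rnea(model_ptr(model), q, qd, qdd, gravity))
}

#' Total mechanical energy of the skeleton
#'
#' @param model A `walker_model`.
#' @param state List with `q` and `qd`.
#' @return Kinetic plus gravitational potential energy (J).
#' @export
mechanical_energy <- function(model, state) {
  wk_energy(model_ptr(model), state$q, state$qd)
}

#' Ground contact forces
#'
#' Nonlinear spring-damper normal force with velocity-dependent damping and
#' regularized Coulomb friction, evaluated per contact sphere.
#'
#' @param model A `walker_model`.
#' @param state List with `q` and `qd`.
#' @return A tibble with one row per contact sphere: sphere index, foot,
#'   force components (N), contact flag, penetration (m) and centre
#'   position; the centre-of-pressure coordinates and per-foot vertical
#'   loads are attached as attributes `cop` and `fz`.
#' @export
contact_model <- function(model, state) {
  res <- wk_contact(model_ptr(model), state$q, state$qd)
  ps <- res$per_sphere
  ns <- nrow(ps)
  out <- tibble::tibble(
    sphere = seq_len(ns),
    foot = rep(c("left", "right"), each = ns / 2),
    fx = ps[, 1], fy = ps[, 2], fz = ps[, 3],
    contact = ps[, 4] > 0,
    penetration = ps[, 5],
    cx = ps[, 6], cy = ps[, 7], cz = ps[, 8]
  )
  attr(out, "cop") <- c(x = res$cop_x, y = res$cop_y)
  attr(out, "fz") <- c(left = res$fz_left, right = res$fz_right)
  out
}

#' Trunk center-of-mass Jacobian of the stance chain
#'
#' Maps the five stance-chain joint rates (hip flexion, hip abduction, knee,
#' ankle, ball-of-foot hinge) to the translational and rotational velocity
#' of the trunk center of mass, with the stance foot held fixed. The
#' ball-of-foot hinge is kinematic only: it is used in this Jacobian and the
#' corresponding mass-matrix rows, not simulated as a degree of freedom.
#'
#' @param model A `walker_model`.
#' @param state List with `q` and `qd`.
#' @param stance_side `"left"` or `"right"`.
#' @return 6 x 5 matrix with rows `v_x, v_y, v_z, w_x, w_y, w_z` and columns
#'   `hipfl, hipab, knee, ankle, ball`.
#' @export
trunk_com_jacobian <- function(model, state, stance_side) {
  side <- match.arg(stance_side, c("left", "right"))
  res <- wk_chain(model_ptr(model), state$q, state$qd,
                  if (side == "left") 0L else 1L)
  J <- res$J
  dimnames(J) <- list(c("v_x", "v_y", "v_z", "w_x", "w_y", "w_z"),
                      c("hipfl", "hipab", "knee", "ankle", "ball"))
  J
}

#' Stance-chain mass matrix
#'
#' The 5 x 5 mass matrix of the stance chain rooted at the ball-of-foot
#' contact, carrying the foot, shank, thigh and the composite trunk plus
#' swing leg. Rows `m_ball` and `m_hipab` are the constraint rows of the
#' propulsion inverse kinematics.
#'
#' @inheritParams trunk_com_jacobian
#' @return 5 x 5 symmetric matrix, rows/columns
#'   `hipfl, hipab, knee, ankle, ball`.
#' @export
stance_chain_mass <- function(model, state, stance_side) {
  side <- match.arg(stance_side, c("left", "right"))
  res <- wk_chain(model_ptr(model), state$q, state$qd,
                  if (side == "left") 0L else 1L)
  M <- res$M_chain
  dimnames(M) <- list(c("hipfl", "hipab", "knee", "ankle", "ball"),
                      c("hipfl", "hipab", "knee", "ankle", "ball"))
  M
}
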