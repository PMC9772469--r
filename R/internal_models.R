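#' Stance-leg inverse dynamics
#'
#' Approximate torque command for the stance chain:
#' `tau = M_chain %*% qdd_des`, omitting gravitational and
#' velocity-dependent terms (gravity is countered by the spinal reflexes,
#' and the stance leg moves slowly). The ball-of-foot entry is ~0 by
#' construction of the propulsion plan and is disregarded downstream.
#'
#' @param qdd_des Desired stance-chain accelerations (length 5, order
#'   `hipfl, hipab, knee, ankle, ball`).
#' @param M_chain Stance-chain mass matrix from [stance_chain_mass()],
#'   built from the (delayed) sensed configuration.
#' @return Torque vector (length 5, N m).
#' @export
inverse_dynamics_stance <- function(qdd_des, M_chain) {
  stopifnot(length(qdd_des) == 5)
  drop(M_chain %*% qdd_des)
}

#' Swing-leg inverse dynamics
#'
#' Full inverse dynamics of the 4-joint swing chain (hip flexion, hip
#' abduction, knee, ankle), including gravitational and interaction
#' terms, treating the pelvis as a moving base (the chain inherits the
#' trunk's angular velocity; base linear acceleration is neglected).
#'
#' @param model A `walker_model`.
#' @param state Full-body state (`q`, `qd`).
#' @param swing_side `"left"` or `"right"`.
#' @param qdd_des Desired accelerations, order `hipfl, hipab, knee, ankle`.
#' @param base_motion Include the trunk's angular velocity (default TRUE).
#' @return Torque vector (length 4, N m), same order.
#' @export
inverse_dynamics_swing <- function(model, state, swing_side, qdd_des,
                                   base_motion = TRUE) {
  side <- match.arg(swing_side, c("left", "right"))
  stopifnot(length(qdd_des) == 4)
  tau <- wk_swing_id(model_ptr(model), state$q, state$qd,
                     if (side == "left") 0L else 1L, qdd_des, base_motion)
  setNames(as.numeric(tau), c("hipfl", "hipab", "knee", "ankle"))
}

#' Muscle force distribution
#'
#' Solves the redundant force-sharing problem: among all nonnegative
#' muscle-force vectors that realize the desired joint torques through
#' the moment-arm matrix (`R F = tau`), select the one minimizing the
#' total squared muscle force. Solved by a dedicated active-set method on
#' the KKT system; torque demands outside the feasible cone fall back to
#' a clamped least-squares solution with a warning.
#'
#' @param tau Desired joint torques (length = rows of `R`).
#' @param R Moment-arm matrix (joints x muscles), e.g. from
#'   [moment_arm_matrix()].
#' @param upper Optional per-muscle upper bounds (e.g. the current force
#'   capacity); `NULL` for the unbounded problem.
#' @return Numeric vector of muscle forces (>= 0) with attributes
#'   `residual` (`||R F - tau||`) and `feasible`.
#' @export
distribute_forces <- function(tau, R, upper = NULL) {
  stopifnot(length(tau) == nrow(R))
  if (is.null(upper)) {
    res <- wk_qp(R, tau)
  } else {
    stopifnot(length(upper) == ncol(R), all(upper >= 0))
    res <- wk_qp_bounded(R, tau, upper)
  }
  if (!res$feasible) {
    warning("torque demand infeasible; clamped least-squares fallback")
  }
  out <- as.numeric(res$F)
  attr(out, "residual") <- res$residual
  attr(out, "feasible") <- res$feasible
  out
}

#' Invert the Hill muscle characteristics
#'
#' Stimulation needed for a desired muscle force at the current (sensed)
#' fiber state: `S = F / (F_max f_l(l_ce) f_v(v_ce))`, clamped to [0, 1].
#' When the force-generating capacity factor `f_l f_v` falls below the
#' guard the muscle cannot produce meaningful force and the stimulation
#' saturates at 1 (with a warning).
#'
#' @param F_des Desired force (N, >= 0).
#' @param F_max Maximal isometric force (N).
#' @param f_l,f_v Force-length and force-velocity factors at the sensed
#'   fiber length and velocity.
#' @param guard Minimum `f_l * f_v` (default 0.05).
#' @return Stimulation in [0, 1].
#' @export
invert_muscle <- function(F_des, F_max, f_l, f_v, guard = 0.05) {
  g <- f_l * f_v
  if (any(g <= guard & F_des > 0)) {
    warning("muscle in unproducible region; stimulation capped at 1")
  }
  ifelse(g <= guard, ifelse(F_des > 0, 1, 0),
         pmin(pmax(F_des / (F_max * g), 0), 1))
}

#' Invert the stretch reflex
#'
#' Descending threshold shift that makes the static stretch reflex
#' reproduce a desired stimulation exactly: `u = (S + h) / K_l - l_ce`.
#' The round trip `stretch_reflex(l, 0, invert_reflex(S, ...), 0, ...)`
#' returns `S` identically.
#'
#' @param S_des Desired stimulation.
#' @param h Resting level.
#' @param K_l Length gain (> 0).
#' @param lce Fiber length used as the reference (the simulator feeds the
#'   planned fiber length here).
#' @return Threshold shift `u`.
#' @export
invert_reflex <- function(S_des, h, K_l, lce) {
  stopifnot(all(K_l > 0))
  (S_des + h) / K_l - lce
}
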