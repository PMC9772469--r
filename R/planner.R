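#' Gait-phase finite state machine (single update)
#'
#' Advances the per-leg phase record by one control tick. Transitions:
#' a swing leg enters stance on ground contact of its foot (after a
#' minimum share of the swing time, so scuffs at lift-off are ignored);
#' early swing becomes late swing when the early share of the swing time
#' has elapsed; a stance leg enters early swing once the contralateral
#' leg has touched down and push-off has completed (own load below a
#' threshold, or a timeout after contralateral touchdown).
#'
#' @param phase A list/tibble row per leg with `phase`
#'   (`"stance" | "early_swing" | "late_swing"`), `phase_t` (s) and
#'   `contra_td` (time of contralateral touchdown, `NA` if none).
#' @param contact Named logical vector `c(left=, right=)`: foot loaded?
#' @param load Named numeric vector of vertical foot loads (N).
#' @param t Current time (s).
#' @param t_swing Swing duration parameter (s).
#' @param dt Control tick (s).
#' @param opts FSM settings (defaults as shipped): `early_share`,
#'   `min_stance`, `min_swing_frac`, `unload_frac`, `pushoff_timeout`,
#'   `body_weight`.
#' @return Updated phase record (same shape), with `phase_t` advanced.
#' @export
fsm_step <- function(phase, contact, load, t, t_swing, dt,
                     opts = list(early_share = 0.5, min_stance = 0.2,
                                 min_swing_frac = 0.25, unload_frac = 0.25,
                                 pushoff_timeout = 0.15,
                                 body_weight = 80 * 9.81)) {
  legs <- c("left", "right")
  out <- phase
  for (leg in legs) {
    contra <- setdiff(legs, leg)
    p <- phase[[leg]]
    pc <- phase[[contra]]
    if (p$phase == "stance") {
      if (is.na(p$contra_td) && pc$phase == "stance" &&
          pc$phase_t < p$phase_t && contact[[contra]]) {
        p$contra_td <- t
      }
      unloaded <- load[[leg]] < opts$unload_frac * opts$body_weight
      pushoff <- !is.na(p$contra_td) &&
        (unloaded || (t - p$contra_td) > opts$pushoff_timeout)
      contra_loaded <- load[[contra]] > 0.35 * opts$body_weight
      if (contra_loaded && pushoff && p$phase_t >= opts$min_stance &&
          pc$phase == "stance") {
        p$phase <- "early_swing"; p$phase_t <- 0; p$contra_td <- NA
      }
    } else if (p$phase == "early_swing") {
      if (p$phase_t >= opts$early_share * t_swing) {
        p$phase <- "late_swing"
      } else if (contact[[leg]] && p$phase_t >= opts$min_swing_frac * t_swing) {
        p$phase <- "stance"; p$phase_t <- 0; p$contra_td <- NA
      }
    } else if (p$phase == "late_swing") {
      if (contact[[leg]] && p$phase_t >= opts$min_swing_frac * t_swing) {
        p$phase <- "stance"; p$phase_t <- 0; p$contra_td <- NA
      }
    }
    p$phase_t <- p$phase_t + dt
    out[[leg]] <- p
  }
  out
}

#' Minimal-jerk trajectory
#'
#' Quintic polynomial from the current state `(x0, v0, a0)` to the goal
#' `(x_goal, 0, 0)` in time `T`, minimizing integrated squared jerk among
#' all trajectories satisfying those boundary conditions. Evaluated at
#' time `t` from the (re)planning instant; replanning every control tick
#' keeps position and velocity continuous.
#'
#' @param x0,v0,a0 Current position, velocity, acceleration.
#' @param x_goal Goal position (zero end velocity and acceleration).
#' @param T_remaining Remaining movement time (> 0).
#' @param t Evaluation time(s) in `[0, T_remaining]`.
#' @return A tibble with `t`, `x`, `v`, `a`.
#' @export
minimal_jerk <- function(x0, v0, a0, x_goal, T_remaining, t) {
  stopifnot(T_remaining > 0)
  T <- T_remaining
  A <- rbind(c(T^3, T^4, T^5),
             c(3 * T^2, 4 * T^3, 5 * T^4),
             c(6 * T, 12 * T^2, 20 * T^3))
  b <- c(x_goal - x0 - v0 * T - a0 * T^2 / 2, -(v0 + a0 * T), -a0)
  cf <- solve(A, b)
  x <- x0 + v0 * t + a0 * t^2 / 2 + cf[1] * t^3 + cf[2] * t^4 + cf[3] * t^5
  v <- v0 + a0 * t + 3 * cf[1] * t^2 + 4 * cf[2] * t^3 + 5 * cf[3] * t^4
  a <- a0 + 6 * cf[1] * t + 12 * cf[2] * t^2 + 20 * cf[3] * t^3
  tibble::tibble(t = t, x = x, v = v, a = a)
}

#' Balance-modulated swing targets
#'
#' The swing hip target is modulated by a feedback law on the delayed
#' horizontal offset between trunk and center of pressure, its velocity,
#' and the delayed trunk orientation:
#' `theta = theta_tar + c_d d + c_v v - phi_trunk`. Applied independently
#' in the sagittal and frontal planes; knee and ankle targets pass through
#' unmodulated.
#'
#' @param params A `walker_params` list (control targets + balance gains).
#' @param d_sag,v_sag Sagittal trunk-CoP offset (m) and its velocity (m/s).
#' @param d_fro,v_fro Frontal-plane equivalents.
#' @param phi_pitch,phi_roll Delayed trunk pitch/roll (rad).
#' @param subphase `"early"` or `"late"`.
#' @param swing_leg `"left"` or `"right"` (flips the frontal sign so that
#'   positive means outward for either leg).
#' @return Named vector: `hipfl`, `hipab`, `knee`, `ankle` target angles.
#' @export
swing_targets <- function(params, d_sag, v_sag, d_fro, v_fro,
                          phi_pitch, phi_roll,
                          subphase = c("early", "late"),
                          swing_leg = c("left", "right")) {
  subphase <- match.arg(subphase)
  swing_leg <- match.arg(swing_leg)
  ba <- params$balance
  co <- params$control
  if (subphase == "early") {
    cd_s <- ba$cd_early_sag; cv_s <- ba$cv_early_sag
    cd_f <- ba$cd_early_fro; cv_f <- ba$cv_early_fro
    hip_tar <- co$theta_hipfl_early; knee_tar <- co$theta_knee_early
  } else {
    cd_s <- ba$cd_late_sag; cv_s <- ba$cv_late_sag
    cd_f <- ba$cd_late_fro; cv_f <- ba$cv_late_fro
    hip_tar <- co$theta_hipfl_late; knee_tar <- co$theta_knee_late
  }
  sgn <- if (swing_leg == "left") 1 else -1
  c(hipfl = hip_tar + cd_s * d_sag + cv_s * v_sag - phi_pitch,
    hipab = sgn * (cd_f * d_fro + cv_f * v_fro - phi_roll),
    knee = knee_tar,
    ankle = co$theta_ankle)
}

#' Propulsion plan: constrained stance inverse kinematics
#'
#' Maps the desired constant forward trunk acceleration into desired
#' accelerations of the five stance-chain joints. The system stacks the
#' forward-translation and sagittal-rotation rows of the trunk CoM
#' Jacobian with the ball-of-foot and hip-abduction rows of the
#' stance-chain mass matrix, so that the solution produces the desired
#' forward acceleration with zero trunk angular acceleration and zero
#' torque at the unactuated ball hinge and at the hip abduction joint.
#' The velocity-dependent term of the acceleration map is neglected.
#' Solved by the Moore-Penrose pseudoinverse (minimum-norm least-squares
#' solution). The stacked system is structurally rank-deficient — the
#' ball-hinge row satisfies an exact momentum identity with the other
#' rows — but the degenerate direction carries no demand, so the
#' propulsion and zero-torque constraints are still met exactly; a
#' posture where the task itself becomes unreachable is reported with a
#' warning.
#'
#' @param J Stance-chain trunk CoM Jacobian (6 x 5), from
#'   [trunk_com_jacobian()].
#' @param M_chain Stance-chain mass matrix (5 x 5), from
#'   [stance_chain_mass()].
#' @param a_x Desired forward acceleration (m/s^2).
#' @return List with `qdd` (desired accelerations, named as the chain),
#'   `tau` (= `M_chain %*% qdd`, with the ball entry ~0) and `residual`
#'   (infinity norm of the constraint violation).
#' @export
propulsion_plan <- function(J, M_chain, a_x) {
  A <- rbind(j_x = J[1, ], j_rz = J[6, ],
             m_ball = M_chain["ball", ], m_hipab = M_chain["hipab", ])
  b <- c(a_x, 0, 0, 0)
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  d_inv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  qdd <- drop(sv$v %*% (d_inv * (t(sv$u) %*% b)))
  names(qdd) <- colnames(M_chain)
  tau <- drop(M_chain %*% qdd)
  resid <- max(abs(A %*% qdd - b))
  if (resid > 1e-8 * max(1, abs(a_x))) {
    warning("singular stance posture; propulsion demand unreachable, ",
            "minimum-norm least-squares solution used")
  }
  list(qdd = qdd, tau = tau, residual = resid)
}
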