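#' Generic stretch reflex
#'
#' Monosynaptic length/velocity feedback with a descending threshold
#' shift: `S_STR = [K_l (l + u) + K_v (v + u_dot) - h]_+`. The descending
#' command `u` shifts the reflex threshold so that the spinal loop
#' executes the motor plan; with `u` from [invert_reflex()] the static
#' round trip is exact.
#'
#' @param lce Sensed contractile-element length (delayed), in the same
#'   length units used for `u` (the simulator uses lengths normalized by
#'   the optimal fiber length).
#' @param vce Sensed lengthening velocity (delayed).
#' @param u Descending threshold shift.
#' @param udot Rate of change of `u` (numerical derivative across control
#'   ticks).
#' @param K_l,K_v,h Length gain, velocity gain and resting level (shared
#'   across muscles).
#' @return Stimulation component `S_STR >= 0`.
#' @export
stretch_reflex <- function(lce, vce, u, udot, K_l, K_v, h) {
  pmax(K_l * (lce + u) + K_v * (vce + udot) - h, 0)
}

#' Force-modulated compliant hip stimulation
#'
#' Trunk-balance reflex: the biarticular hip muscles are stimulated in
#' proportion to the sensed leg force and the rectified deviation of the
#' stance hip flexion angle from its reference — a spring whose stiffness
#' scales with leg loading. The hamstrings receive the flexion-error side
#' and the rectus femoris the extension-error side, so the resulting hip
#' torque opposes trunk pitch deviations in both directions. Stance phase
#' only; inputs are delay-line reads.
#'
#' @param F_s Sensed leg force (N), from [leg_force_estimate()].
#' @param theta_hipfl Sensed stance hip flexion angle (rad, delayed).
#' @param theta_ref Reference hip flexion angle (descending command, rad).
#' @param c_ham,c_rf Gains (1/N).
#' @return Named vector with components `HAM` and `RF`.
#' @export
fmch_stimulation <- function(F_s, theta_hipfl, theta_ref, c_ham, c_rf) {
  err <- theta_hipfl - theta_ref
  c(HAM = c_ham * F_s * max(0, err),
    RF = c_rf * F_s * max(0, -err))
}

#' Leg force estimate from antigravity muscle forces
#'
#' Approximates the force the stance leg applies to the trunk from the
#' Golgi-tendon-organ signals of the two monoarticular antigravity
#' muscles: `F_s = (F_VAS m_VAS + F_SOL m_SOL) / 0.032`, where 0.032 m is
#' the lever arm approximating the transformation from joint torques to a
#' force acting at the hip.
#'
#' @param F_vas,F_sol Muscle forces (N), delayed.
#' @param m_vas,m_sol Moment-arm magnitudes (m).
#' @return Leg force `F_s` in N.
#' @export
leg_force_estimate <- function(F_vas, m_vas, F_sol, m_sol) {
  stopifnot(all(F_vas >= 0), all(F_sol >= 0), all(m_vas > 0), all(m_sol > 0))
  (F_vas * m_vas + F_sol * m_sol) / 0.032
}

#' Compliant-leg stimulation (positive force feedback)
#'
#' Antigravity stance muscles are stimulated in proportion to their own
#' delayed force, producing compliant leg behavior that counters gravity
#' without explicit gravity compensation. Zero during swing.
#'
#' @param F_hat Delayed own-muscle force (N).
#' @param gain Feedback gain (1/N).
#' @param stance Logical: is the leg in stance?
#' @return Stimulation component `S_CL`.
#' @export
compliant_leg_stimulation <- function(F_hat, gain, stance = TRUE) {
  ifelse(stance, gain * pmax(F_hat, 0), 0)
}

#' Knee-overextension prevention stimulation
#'
#' Guard reflex on the knee flexors: active only when the knee is within a
#' margin of full extension while extending, growing with both proximity
#' to the limit and extension velocity. Stance phase only.
#'
#' @param knee Knee flexion angle (rad; 0 = straight).
#' @param knee_vel Knee angular velocity (rad/s; negative = extending).
#' @param margin Activation margin (rad).
#' @param k_pos Position gain (1/rad).
#' @param k_vel Velocity gain (s/rad).
#' @param stance Logical.
#' @return Stimulation component `S_PKO`.
#' @export
knee_overextension_stimulation <- function(knee, knee_vel, margin, k_pos,
                                           k_vel, stance = TRUE) {
  on <- stance & knee < margin & knee_vel < 0
  ifelse(on, pmax(margin - knee, 0) * (k_pos + k_vel * pmax(-knee_vel, 0)), 0)
}

#' Combine stimulation components
#'
#' Total motorneural stimulation: the rectified sum of the stretch-reflex,
#' trunk-balance, compliant-leg and knee-guard components, clamped between
#' the tonic floor and 1. During swing only the stretch reflex drives the
#' muscles, so the other components must be zero there.
#'
#' @param S_STR,S_FMCH,S_CL,S_PKO Component stimulations.
#' @param floor Stimulation floor (default 0.001).
#' @return Total stimulation in `[floor, 1]`.
#' @export
combine_stimulations <- function(S_STR, S_FMCH = 0, S_CL = 0, S_PKO = 0,
                                 floor = 0.001) {
  s <- pmax(S_STR + S_FMCH + S_CL + S_PKO, 0)
  pmin(pmax(s, floor), 1)
}
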