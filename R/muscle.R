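#' Muscle-tendon unit parameters
#'
#' Convenience constructor for a standalone Hill-type muscle-tendon unit
#' (contractile element with Gaussian-like force-length and hyperbolic
#' force-velocity characteristics, series elastic element with a
#' quadratic toe region, parallel elastic element).
#'
#' @param fmax Maximal isometric force (N).
#' @param lopt Optimal contractile-element length (m).
#' @param lslack Tendon slack length (m).
#' @param vmax_rel Maximal shortening velocity in optimal lengths per
#'   second.
#' @param tau_act,tau_deact Activation/deactivation time constants (s).
#' @return A list usable by [step_muscle()].
#' @export
muscle_tendon_unit <- function(fmax, lopt, lslack, vmax_rel = 12,
                               tau_act = 0.011, tau_deact = 0.04) {
  stopifnot(fmax > 0, lopt > 0, lslack > 0, vmax_rel > 0,
            tau_act > 0, tau_deact > 0)
  list(fmax = fmax, lopt = lopt, lslack = lslack, vmax_rel = vmax_rel,
       tau_act = tau_act, tau_deact = tau_deact)
}

hill_constants <- function(model = NULL) {
  if (is.null(model)) {
    list(fl_w = 0.56, fl_c = log(0.05), fv_K = 5, fv_N = 1.5,
         see_eps_ref = 0.04, pe_w = 0.8)
  } else {
    model$cfg$hill
  }
}

#' Initialize a muscle state
#'
#' @param mtu From [muscle_tendon_unit()].
#' @param l_mtu Muscle-tendon length (m).
#' @param a0 Initial activation.
#' @param hill Hill shape constants (defaults as shipped).
#' @return Muscle state list (`a`, `lce`, `vce`, `F`).
#' @export
init_muscle <- function(mtu, l_mtu, a0 = 0.01, hill = hill_constants()) {
  wk_muscle_init(mtu, l_mtu, a0, hill)
}

#' Advance a Hill-type muscle by one time step
#'
#' Activation relaxes toward the stimulation with first-order dynamics;
#' the contractile-element velocity is the one at which the active force
#' (activation x F_max x f_l x f_v) plus the parallel elastic force
#' balances the series elastic tendon force; the muscle force output is
#' the tendon force.
#'
#' @param mtu From [muscle_tendon_unit()].
#' @param state Muscle state from [init_muscle()] or a previous step.
#' @param S Stimulation in [0, 1].
#' @param l_mtu Current muscle-tendon length (m); must be finite.
#' @param dt Time step (s, > 0).
#' @param hill Hill shape constants.
#' @return Updated state with `a`, `lce`, `vce`, `F`, `fl`, `fv`.
#' @export
step_muscle <- function(mtu, state, S, l_mtu, dt, hill = hill_constants()) {
  stopifnot(dt > 0, S >= 0, S <= 1)
  if (!is.finite(l_mtu)) stop("non-finite muscle-tendon length")
  wk_muscle_step(mtu, state, S, l_mtu, dt, hill)
}

#' Force-length and force-velocity characteristics
#'
#' @param lce Contractile-element length (m).
#' @param vce Lengthening velocity (m/s).
#' @param mtu From [muscle_tendon_unit()].
#' @param hill Hill shape constants.
#' @return Named vector `c(f_l, f_v)`.
#' @export
muscle_characteristics <- function(lce, vce, mtu, hill = hill_constants()) {
  v <- wk_fl_fv(lce, vce, mtu, hill)
  c(f_l = v[1], f_v = v[2])
}

#' Moment-arm matrix
#'
#' Signed moment arms of every muscle about every actuated joint at the
#' current configuration, consistent with the muscle-tendon length
#' functions by the tendon-excursion relationship `R = -d l_mtu / d q`.
#' Positive arms produce positive joint torque (flexion at hip and knee,
#' dorsiflexion at the ankle, abduction at the hip ab/adduction joint),
#' so joint torques are `tau = R %*% F`.
#'
#' @param model A `walker_model`.
#' @param state Full-body state (uses `q`).
#' @return 8 x 20 matrix (joints x muscles) with dimnames.
#' @export
moment_arm_matrix <- function(model, state) {
  g <- wk_muscle_geometry(model_ptr(model), state$q)
  R <- g$R
  side <- ifelse(model$info$muscle_leg == 0, "l", "r")
  dimnames(R) <- list(joint_names(),
                      paste0(model$info$muscle_names, "_", side))
  R
}

#' Muscle-tendon lengths at a configuration
#'
#' @inheritParams moment_arm_matrix
#' @return Named numeric vector (20 muscles).
#' @export
muscle_lengths <- function(model, state) {
  g <- wk_muscle_geometry(model_ptr(model), state$q)
  side <- ifelse(model$info$muscle_leg == 0, "l", "r")
  setNames(as.numeric(g$lmtu),
           paste0(model$info$muscle_names, "_", side))
}
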