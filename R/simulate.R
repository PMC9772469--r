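#' Initial state for walking
#'
#' Deterministic mid-gait initial condition at the double-support instant:
#' the right leg has just touched down ahead (hip flexed, knee slightly
#' bent) and carries the load, the left leg trails with its toe barely on
#' the ground (about to push off), the trunk leans slightly forward, and
#' the body moves forward at `v_init`. The gait-phase machine starts the
#' trailing leg in pre-swing.
#'
#' @param model A `walker_model`.
#' @param params A `walker_params` list (uses `v_init`).
#' @param hip_lead,knee_lead Leading-leg posture (rad).
#' @param hip_trail,knee_trail Trailing-leg posture (rad).
#' @param pitch Initial trunk pitch (rad).
#' @return A list with `q` and `qd`.
#' @export
walking_initial_state <- function(model, params, hip_lead = 0.35,
                                  knee_lead = 0.20, hip_trail = -0.25,
                                  knee_trail = 0.35, pitch = 0.05) {
  q <- numeric(14)
  q[5] <- pitch
  q[12] <- hip_lead; q[13] <- knee_lead; q[14] <- 0.05
  q[8] <- hip_trail; q[9] <- knee_trail; q[10] <- -0.25
  q[3] <- 1.2
  # drop the body until the leading (right) foot penetrates 3 mm
  cc <- wk_contact(model_ptr(model), q, numeric(14))
  zmin_r <- min(cc$per_sphere[5:8, 8] - model$cfg$foot$spheres[[1]]$radius)
  q[3] <- q[3] - zmin_r - 0.003
  # rotate the trailing ankle until its toe clears the ground by ~1.5 cm
  # (the body settles about a centimetre while the leading tendons load)
  r <- model$cfg$foot$spheres[[1]]$radius
  for (it in 1:40) {
    cc <- wk_contact(model_ptr(model), q, numeric(14))
    zl <- min(cc$per_sphere[1:4, 8] - r)
    if (zl > 0.02 && zl < 0.03) break
    q[10] <- q[10] + if (zl < 0.02) 0.02 else -0.02
    if (q[10] > 0.4 || q[10] < -0.85) break
  }
  qd <- numeric(14)
  qd[1] <- params$control$v_init
  list(q = q, qd = qd)
}

#' Run a closed-loop walking simulation
#'
#' Simulates the full sensorimotor loop: delayed proprioceptive and
#' balance feedback, the gait-phase finite state machine, minimal-jerk
#' swing plans and the propulsion plan, the internal inverse models
#' (inverse dynamics, muscle-force distribution, Hill and stretch-reflex
#' inversion), the spinal reflex modules, Hill-type muscle dynamics, and
#' the 14-DoF skeletal dynamics with ground contact. Fixed-step integration
#' at `params$sim$dt` with control updates every `params$sim$control_dt`.
#' The run is deterministic: identical inputs give identical records.
#'
#' @param params A `walker_params` list (see [default_params()]).
#' @param model A `walker_model`; default [load_model()].
#' @param duration Simulated duration in seconds (ends early on a fall).
#' @param init Initial state list (`q`, `qd`); default
#'   [walking_initial_state()].
#' @param log_muscles Record per-muscle time series (default `TRUE`).
#' @return A `walker_sim` object: tibbles `states`, `grf`, `muscles`
#'   (optional), `heel_strikes`, `transitions`; `fall` (`NULL` or a list
#'   with `time`, `x_fall`, `cause`); scalars `t_end`, `x_walked`,
#'   `max_propulsion_residual`; and the `params` used.
#' @examples
#' \donttest{
#' sim <- run_simulation(default_params(), duration = 2)
#' sim$t_end
#' }
#' @export
run_simulation <- function(params, model = load_model(), duration = 20,
                           init = NULL, log_muscles = TRUE) {
  stopifnot(duration > 0)
  if (is.null(init)) init <- walking_initial_state(model, params)
  raw <- wk_simulate(model_ptr(model), params, duration, init,
                     log_muscles, TRUE)
  as_walker_sim(raw, model, params, duration, log_muscles)
}

as_walker_sim <- function(raw, model, params, duration, log_muscles) {
  qn <- coordinate_names()
  st <- tibble::as_tibble(as.data.frame(raw$states))
  names(st) <- c("time", qn, paste0("d_", qn))
  grf <- tibble::as_tibble(as.data.frame(raw$grf))
  names(grf) <- c("fz_left", "fz_right", "cop_x", "cop_y",
                  "propulsion_residual", "com_x")
  grf$time <- st$time
  hs <- raw$heel_strikes
  heel <- tibble::tibble(
    time = if (length(hs)) hs[, 1] else numeric(),
    leg = if (length(hs)) c("left", "right")[hs[, 2] + 1] else character(),
    x = if (length(hs)) hs[, 3] else numeric(),
    y = if (length(hs)) hs[, 4] else numeric()
  )
  tr <- raw$transitions
  phase_names <- c("stance", "early_swing", "late_swing")
  trans <- tibble::tibble(
    time = if (length(tr)) tr[, 1] else numeric(),
    leg = if (length(tr)) c("left", "right")[tr[, 2] + 1] else character(),
    from = if (length(tr)) phase_names[tr[, 3] + 1] else character(),
    to = if (length(tr)) phase_names[tr[, 4] + 1] else character()
  )
  muscles <- NULL
  if (log_muscles && length(raw$muscle_log)) {
    mn <- as.character(model$info$muscle_names)
    side <- ifelse(model$info$muscle_leg == 0, "l", "r")
    cols <- as.vector(outer(c("a", "F", "S", "S_STR", "S_FMCH", "S_CL",
                              "S_PKO", "lce_n"),
                            paste0(mn, "_", side), paste, sep = "."))
    ml <- raw$muscle_log
    # columns are grouped per muscle (8 quantities each)
    muscles <- tibble::as_tibble(as.data.frame(ml))
    names(muscles) <- as.vector(vapply(seq_along(mn), function(i) {
      paste0(c("a", "F", "S", "S_STR", "S_FMCH", "S_CL", "S_PKO", "lce_n"),
             ".", mn[i], "_", side[i])
    }, character(8)))
    muscles$time <- st$time
  }
  fall <- raw$fall
  if (!is.null(fall)) {
    fall$cause <- c("height", "tilt", "numerical")[fall$cause]
  }
  structure(list(
    states = st, grf = grf, muscles = muscles,
    heel_strikes = heel, transitions = trans,
    fall = fall, t_end = raw$t_end, x_walked = raw$x_walked,
    max_propulsion_residual = raw$max_propulsion_residual,
    qp_infeasible = raw$qp_infeasible,
    stim_range = raw$stim_range,
    flight_anomalies = raw$flight_anomalies,
    final_state = list(q = as.numeric(raw$final_q),
                       qd = as.numeric(raw$final_qd)),
    params = params, duration = duration
  ), class = "walker_sim")
}

#' @export
print.walker_sim <- function(x, ...) {
  cat("<walker_sim>\n")
  cat(sprintf("  simulated %.2f s of %.2f s requested; walked %.2f m\n",
              x$t_end, x$duration, x$x_walked))
  if (is.null(x$fall)) {
    cat("  no fall\n")
  } else {
    cat(sprintf("  fell at t = %.2f s (x = %.2f m, cause: %s)\n",
                x$fall$time, x$fall$x_fall, x$fall$cause))
  }
  cat(sprintf("  heel strikes: %d\n", nrow(x$heel_strikes)))
  invisible(x)
}

#' Fall detection rule
#'
#' A simulation state counts as fallen when the trunk center of mass drops
#' below a fraction of its standing height or the trunk tilts beyond a
#' pitch/roll limit. The same rule terminates [run_simulation()] runs;
#' this function exposes it for single states.
#'
#' @param model A `walker_model`.
#' @param state List with `q` (and optionally `qd`).
#' @param height_frac,max_tilt Thresholds (defaults as in the shipped
#'   parameter file: 70% of standing height, 60 degrees).
#' @return Logical.
#' @export
detect_fall <- function(model, state, height_frac = 0.70,
                        max_tilt = 60 * pi / 180) {
  f <- wk_fk(model_ptr(model), state$q,
             if (is.null(state$qd)) numeric(14) else state$qd)
  trunk_z <- f$trunk_com[3]
  trunk_z < height_frac * model$info$standing_z ||
    abs(state$q[5]) > max_tilt || abs(state$q[6]) > max_tilt
}
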