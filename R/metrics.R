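#' Gait metrics from a simulation record
#'
#' Measures step length, cadence, speed and steadiness over an evaluation
#' window (by default the last 10 s of the record, following the
#' convention of evaluating 20 s walks over their second half).
#'
#' Definitions: cadence is the inverse mean inter-strike interval in
#' steps/min; step length is the mean anterior distance between
#' consecutive contralateral heel-strike positions; speed is the mean
#' forward velocity of the whole-body center of mass; `d_steady` is the
#' root-mean-square difference between the kinematic state (generalized
#' coordinates except forward position, plus all velocities) at
#' consecutive same-side heel strikes, averaged over the window — zero for
#' a perfectly periodic gait.
#'
#' @param sim A `walker_sim` from [run_simulation()] or a `gait_events`
#'   fixture from [generate_event_fixture()].
#' @param window Length of the evaluation window in seconds (counted back
#'   from the end of the record).
#' @return A one-row tibble: `step_length` (m), `cadence` (steps/min),
#'   `speed` (m/s), `d_steady`, `x_fall` (m walked before a fall, `NA` if
#'   no fall), `n_steps`, `valid` (at least 3 strikes in the window and no
#'   fall).
#' @export
gait_metrics <- function(sim, window = 10) {
  hs <- sim$heel_strikes
  t_end <- sim$t_end
  t0 <- max(0, t_end - window)
  win_dur <- t_end - t0
  in_win <- hs[hs$time >= t0, , drop = FALSE]
  n <- nrow(in_win)
  fell <- !is.null(sim$fall)
  x_fall <- if (fell) sim$fall$x_fall else NA_real_
  if (n < 3 || win_dur <= 0) {
    return(tibble::tibble(step_length = NA_real_, cadence = NA_real_,
                          speed = NA_real_, d_steady = NA_real_,
                          x_fall = x_fall, n_steps = n, valid = FALSE))
  }
  cadence <- 60 * (n - 1) / (in_win$time[n] - in_win$time[1])
  # anterior distance between consecutive contralateral strikes
  dx <- diff(in_win$x)
  alt <- in_win$leg[-1] != in_win$leg[-n]
  step_length <- mean(dx[alt])
  # mean forward CoM velocity
  speed <- com_speed(sim, t0, t_end)
  d_steady <- steadiness(sim, in_win)
  tibble::tibble(step_length = step_length, cadence = cadence,
                 speed = speed, d_steady = d_steady,
                 x_fall = x_fall, n_steps = n, valid = !fell)
}

com_speed <- function(sim, t0, t1) {
  if (!is.null(sim$grf)) {
    cx <- stats::approx(sim$grf$time, sim$grf$com_x, c(t0, t1), rule = 2)$y
  } else {
    cx <- stats::approx(sim$com$time, sim$com$x, c(t0, t1), rule = 2)$y
  }
  (cx[2] - cx[1]) / (t1 - t0)
}

steadiness <- function(sim, strikes) {
  if (is.null(sim$states)) return(0)
  st <- sim$states
  # kinematic state without absolute forward position
  cols <- c(3:29)
  sm <- as.matrix(st[, -1])
  vals <- numeric(0)
  for (side in unique(strikes$leg)) {
    tt <- strikes$time[strikes$leg == side]
    if (length(tt) < 2) next
    idx <- vapply(tt, function(t) which.min(abs(st$time - t)), integer(1))
    for (k in seq_len(length(idx) - 1)) {
      d <- sm[idx[k + 1], cols - 1] - sm[idx[k], cols - 1]
      vals <- c(vals, sqrt(mean(d^2)))
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Synthetic heel-strike event stream
#'
#' Builds a perfectly periodic gait event record (alternating legs, exact
#' cadence and step length, center of mass advancing at
#' `step_length * cadence / 60`). Used to exercise the gait-metric and
#' cost logic without running a simulation.
#'
#' @param cadence Steps per minute.
#' @param step_length Meters.
#' @param duration Seconds.
#' @return A `gait_events` object accepted by [gait_metrics()].
#' @export
generate_event_fixture <- function(cadence, step_length, duration) {
  stopifnot(cadence > 0, step_length > 0, duration > 0)
  dt_step <- 60 / cadence
  times <- seq(dt_step, duration, by = dt_step)
  n <- length(times)
  structure(list(
    heel_strikes = tibble::tibble(
      time = times,
      leg = rep(c("left", "right"), length.out = n),
      x = step_length * seq_len(n),
      y = rep(c(0.09, -0.09), length.out = n)
    ),
    com = tibble::tibble(
      time = c(0, duration),
      x = c(0, duration * step_length * cadence / 60)
    ),
    states = NULL,
    fall = NULL,
    t_end = duration
  ), class = "gait_events")
}
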