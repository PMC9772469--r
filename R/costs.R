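#' Cost configuration for gait optimization
#'
#' Normalization constants and tolerance margins of the staged cost
#' functions. The constants order the stages so that any falling gait
#' scores worse than any walking one, any off-speed gait worse than any
#' on-speed one, and so on.
#'
#' @param cadence_target Target cadence, steps/min (targeted cost only).
#' @param step_length_target Target step length, m.
#' @return A list with `c0 = 1000`, `c1 = 500`, `c2 = 250`, `c3 = 125`,
#'   speed tolerance `delta_v = 0.02` m/s, cadence tolerance
#'   `delta_cad = 2` steps/min, and the derived speed target
#'   `v_tar = step_length_target * cadence_target / 60`.
#' @export
cost_config <- function(cadence_target = NA, step_length_target = NA) {
  list(c0 = 1000, c1 = 500, c2 = 250, c3 = 125,
       delta_v = 0.02, delta_cad = 2,
       cad_tar = cadence_target, sl_tar = step_length_target,
       v_tar = step_length_target * cadence_target / 60)
}

#' Unconstrained walking cost
#'
#' Two-stage cost for finding basic walking without prescribing a gait:
#' a falling model scores `c0` minus the distance walked before the fall;
#' a surviving model scores `c0/2` plus the steadiness measure, so that
#' every surviving gait outranks every falling one and steadier gaits
#' are preferred.
#'
#' @param metrics One-row tibble from [gait_metrics()].
#' @param fell Logical: did the model fall?
#' @param cfg Cost configuration from [cost_config()].
#' @return Scalar cost.
#' @export
cost_unconstrained <- function(metrics, fell, cfg = cost_config()) {
  if (fell) {
    x <- metrics$x_fall
    if (is.na(x)) x <- 0
    return(cfg$c0 - x)
  }
  d <- metrics$d_steady
  if (is.na(d)) d <- cfg$c0 / 4  # survived but too few steps to measure
  cfg$c0 / 2 + d
}

#' Targeted gait cost
#'
#' Four-stage cost for walking at a prescribed step length and cadence:
#' falls are penalized by distance; then speed error beyond the tolerance
#' `delta_v`; then cadence error beyond `delta_cad`; finally steadiness.
#' Gait parameters are measured over the last 10 s of a 20 s walk.
#'
#' @inheritParams cost_unconstrained
#' @export
cost_targeted <- function(metrics, fell, cfg) {
  stopifnot(is.finite(cfg$v_tar), is.finite(cfg$cad_tar))
  if (fell) {
    x <- metrics$x_fall
    if (is.na(x)) x <- 0
    return(cfg$c0 - x)
  }
  if (!isTRUE(metrics$valid) || is.na(metrics$speed) ||
      is.na(metrics$cadence)) {
    return(cfg$c1 + cfg$v_tar)  # survived without measurable steps
  }
  verr <- abs(metrics$speed - cfg$v_tar)
  if (verr > cfg$delta_v) return(cfg$c1 + verr)
  cerr <- abs(metrics$cadence - cfg$cad_tar)
  if (cerr > cfg$delta_cad) return(cfg$c2 + cerr)
  d <- metrics$d_steady
  if (is.na(d)) d <- 0
  cfg$c3 + d
}

#' Cost stage of a targeted-cost value
#'
#' @param J Cost value from [cost_targeted()].
#' @return Integer 1 (falling), 2 (speed), 3 (cadence) or 4 (steadiness).
#' @export
cost_stage <- function(J) {
  ifelse(J >= 750, 1L, ifelse(J >= 500, 2L, ifelse(J >= 250, 3L, 4L)))
}
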