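#' Synthetic basis-point library
#'
#' Deterministic fixture library for exercising interpolation, transition
#' scheduling and PCA without running optimizations: gait targets are laid
#' out over the cadence 85–140 steps/min by step length 0.53–0.97 m
#' rectangle (the range a walking model of this class achieves), and the
#' control parameters are a smooth affine function of the targets plus
#' optional small noise. Achieved gait values equal the targets, so the
#' fixture behaves like a perfectly converged library.
#'
#' @param n Number of basis points (>= 5).
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation on the affine parameters
#'   (fraction of each parameter's bound range; 0 for an exactly affine
#'   library).
#' @param cadence_range,step_length_range Target rectangle.
#' @return A `gait_library` tibble.
#' @export
generate_fixture_library <- function(n = 20, seed = 1, noise_sd = 0.005,
                                     cadence_range = c(85, 140),
                                     step_length_range = c(0.53, 0.97)) {
  stopifnot(n >= 5)
  set.seed(as.integer(seed))
  cad <- runif(n, cadence_range[1], cadence_range[2])
  sl <- runif(n, step_length_range[1], step_length_range[2])
  # normalized targets in [0, 1]
  u <- (cad - cadence_range[1]) / diff(cadence_range)
  v <- (sl - step_length_range[1]) / diff(step_length_range)
  b <- parameter_bounds("control")
  lo <- setNames(b$lower, b$name); hi <- setNames(b$upper, b$name)
  # affine map from (u, v) into each parameter's range: longer steps mean
  # larger swing targets and propulsion, faster cadence means shorter
  # swing times
  aff <- list(
    theta_hipfl_early = 0.35 + 0.35 * v + 0.05 * u,
    theta_knee_early = 0.75 + 0.30 * v - 0.10 * u,
    theta_hipfl_late = 0.25 + 0.30 * v,
    theta_knee_late = 0.15 + 0.10 * v,
    theta_ankle = 0.05 + 0.10 * v,
    t_swing = 0.75 - 0.35 * u,
    theta_ref_hipfl = 0.05 + 0.10 * v,
    a_x = 0.2 + 0.5 * u + 0.6 * v,
    v_init = sl * cad / 60
  )
  out <- tibble::as_tibble(aff)
  if (noise_sd > 0) {
    for (nm in names(out)) {
      out[[nm]] <- out[[nm]] + rnorm(n, 0, noise_sd * (hi[nm] - lo[nm]))
    }
  }
  for (nm in names(out)) out[[nm]] <- pmin(pmax(out[[nm]], lo[nm]), hi[nm])
  out$cadence <- cad
  out$step_length <- sl
  out$speed <- sl * cad / 60
  gait_library(out)
}
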