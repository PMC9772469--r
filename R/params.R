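#' Load the default control and reflex parameters
#'
#' The parameter file bundles the 27 spinal reflex parameters, the 8 balance
#' feedback gains, the high-level control parameters (8 values + initial
#' speed) that define a gait, and the finite-state-machine, fall-detection
#' and integrator settings.
#'
#' @param path Path to a YAML parameter file; `NULL` loads the package
#'   default.
#' @return A nested list of parameters (class `walker_params`).
#' @export
default_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_params.yaml", package = "gaitplanr")
  }
  p <- yaml::read_yaml(path)
  class(p) <- c("walker_params", "list")
  p
}

#' Extract or replace the high-level control parameter set
#'
#' A gait is defined by 8 control parameters — swing hip-flexion and knee
#' targets at the end of early and late swing, the swing ankle target, the
#' swing time, the stance hip-flexion reference (trunk lean), and the
#' constant forward propulsion — plus the initial speed `v_init`, which is
#' used only at simulation onset and is not a control parameter.
#'
#' @param params A `walker_params` list.
#' @return `control_set()`: a named numeric vector of length 9.
#' @export
control_set <- function(params) {
  unlist(params$control)[control_names()]
}

#' @rdname control_set
#' @param control Named numeric vector (any subset of [control_names()]).
#' @export
set_control <- function(params, control) {
  stopifnot(all(names(control) %in% control_names()))
  for (nm in names(control)) params$control[[nm]] <- unname(control[nm])
  params
}

#' @rdname control_set
#' @export
control_names <- function() {
  c("theta_hipfl_early", "theta_knee_early", "theta_hipfl_late",
    "theta_knee_late", "theta_ankle", "t_swing", "theta_ref_hipfl",
    "a_x", "v_init")
}

# ---- full optimization vector: 8 control + v_init + 8 balance + 27 spinal ----

spinal_names <- function() {
  c("K_l", "K_v", "h", "c_ham", "c_rf", "g_sol", "g_vas", "g_gas",
    "pko_margin", "pko_kp", "pko_kv",
    "s0_sol", "s0_ta", "s0_gas", "s0_vas", "s0_ham", "s0_rf", "s0_glu",
    "s0_hfl", "s0_hab", "s0_had",
    "delay_ankle", "delay_knee", "delay_hip", "stim_floor",
    "tau_act", "tau_deact")
}

balance_names <- function() {
  c("cd_early_sag", "cv_early_sag", "cd_late_sag", "cv_late_sag",
    "cd_early_fro", "cv_early_fro", "cd_late_fro", "cv_late_fro")
}

#' Parameter bounds for optimization
#'
#' Physiologic box bounds for every optimizable parameter: joint-angle
#' targets within anatomical range, swing time 0.25–0.9 s, propulsion
#' 0–3 m/s², reflex gains and tonic drives within the ranges customary for
#' reflex-based walking models.
#'
#' @param subset `"all"` (43 parameters + v_init) or `"control"`
#'   (8 control parameters + v_init).
#' @return A tibble with columns `name`, `lower`, `upper`.
#' @export
parameter_bounds <- function(subset = c("all", "control")) {
  subset <- match.arg(subset)
  ctl <- tibble::tribble(
    ~name, ~lower, ~upper,
    "theta_hipfl_early", 0.2, 1.2,
    "theta_knee_early", 0.3, 1.6,
    "theta_hipfl_late", 0.0, 0.9,
    "theta_knee_late", 0.02, 0.8,
    "theta_ankle", -0.2, 0.45,
    "t_swing", 0.25, 0.9,
    "theta_ref_hipfl", -0.1, 0.4,
    "a_x", 0.0, 3.0,
    "v_init", 0.4, 1.8
  )
  if (subset == "control") return(ctl)
  bal <- tibble::tibble(
    name = balance_names(),
    lower = 0,
    upper = rep(c(1.2, 0.6), 4)
  )
  spi <- tibble::tribble(
    ~name, ~lower, ~upper,
    "K_l", 0.5, 10, "K_v", 0, 1, "h", 0, 0.5,
    "c_ham", 1e-5, 8e-3, "c_rf", 1e-5, 8e-3,
    "g_sol", 0, 8e-4, "g_vas", 0, 6e-4, "g_gas", 0, 8e-4,
    "pko_margin", 0.02, 0.3, "pko_kp", 0, 8, "pko_kv", 0, 2
  )
  s0 <- tibble::tibble(name = spinal_names()[12:21], lower = 0.001, upper = 0.15)
  rest <- tibble::tribble(
    ~name, ~lower, ~upper,
    "delay_ankle", 0.01, 0.03, "delay_knee", 0.005, 0.02,
    "delay_hip", 0.002, 0.01, "stim_floor", 5e-4, 0.01,
    "tau_act", 0.008, 0.02, "tau_deact", 0.02, 0.06
  )
  dplyr::bind_rows(ctl, bal, spi, s0, rest)
}

# pack the optimizable parameters of `params` into a named vector
pack_params <- function(params, subset = c("all", "control")) {
  subset <- match.arg(subset)
  v <- control_set(params)
  if (subset == "control") return(v)
  c(v,
    unlist(params$balance)[balance_names()],
    unlist(params$spinal)[spinal_names()])
}

# write a (named) vector back into the nested parameter list
unpack_params <- function(x, params, subset = c("all", "control")) {
  subset <- match.arg(subset)
  cn <- control_names()
  for (nm in cn) params$control[[nm]] <- unname(x[nm])
  if (subset == "control") return(params)
  for (nm in balance_names()) params$balance[[nm]] <- unname(x[nm])
  for (nm in spinal_names()) params$spinal[[nm]] <- unname(x[nm])
  params
}

#' The shipped optimized gait parameters
#'
#' Best parameter set found by this package's own evolutionary optimization
#' runs (`scripts/optimize_gait.R`), shipped as a regression fixture for the
#' walking experiments.
#'
#' @return A `walker_params` list.
#' @export
optimized_params <- function() {
  default_params(system.file("extdata", "optimized_gait.yaml",
                             package = "gaitplanr"))
}
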