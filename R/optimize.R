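#' Optimize walking parameters
#'
#' Evolutionary optimization of the walker. With `subset = "all"` every
#' optimizable parameter (8 high-level control parameters, 8 balance
#' gains, 27 spinal reflex parameters, plus the initial speed) is tuned
#' against the unconstrained walking cost — the run that establishes a
#' self-selected gait. With `subset = "control"` only the 8 control
#' parameters and the initial speed are tuned against the targeted cost
#' for a prescribed step length and cadence, leaving balance and spinal
#' parameters fixed — the run that "learns" one gait of the basis-point
#' library.
#'
#' @param params Starting `walker_params`.
#' @param subset `"all"` or `"control"`.
#' @param cadence_target,step_length_target Gait targets (required for
#'   `subset = "control"`).
#' @param model A `walker_model`.
#' @param budget Maximum cost-function evaluations.
#' @param seed Integer seed (evaluation is deterministic; the seed drives
#'   CMA-ES sampling).
#' @param duration Simulated seconds per evaluation (metrics over the last
#'   `window` s).
#' @param window Metric window, s.
#' @param sigma0,lambda CMA-ES settings (see [cma_es()]).
#' @param callback Optional per-generation callback.
#' @return A `gait_opt` object: `params` (best parameter list), `best_x`,
#'   `value`, `cma` (the [cma_es()] result), `subset`, `targets`.
#' @export
optimize_gait <- function(params, subset = c("all", "control"),
                          cadence_target = NULL, step_length_target = NULL,
                          model = load_model(), budget = 2000, seed = 1,
                          duration = 20, window = 10,
                          sigma0 = 0.1, lambda = NULL, callback = NULL) {
  subset <- match.arg(subset)
  bounds <- parameter_bounds(if (subset == "all") "all" else "control")
  x0 <- pack_params(params, subset)
  stopifnot(identical(names(x0), bounds$name))
  x0 <- pmin(pmax(x0, bounds$lower), bounds$upper)
  cfg <- NULL
  if (subset == "control") {
    stopifnot(!is.null(cadence_target), !is.null(step_length_target))
    cfg <- cost_config(cadence_target, step_length_target)
  }
  evaluate <- function(x) {
    names(x) <- bounds$name
    p <- unpack_params(x, params, subset)
    sim <- run_simulation(p, model, duration = duration, log_muscles = FALSE)
    met <- gait_metrics(sim, window = window)
    fell <- !is.null(sim$fall)
    if (subset == "all") cost_unconstrained(met, fell)
    else cost_targeted(met, fell, cfg)
  }
  res <- cma_es(evaluate, x0, bounds$lower, bounds$upper, sigma0 = sigma0,
                budget = budget, lambda = lambda, seed = seed,
                callback = callback)
  best <- res$par
  names(best) <- bounds$name
  structure(list(params = unpack_params(best, params, subset),
                 best_x = best, value = res$value, cma = res,
                 subset = subset,
                 targets = c(cadence = cadence_target %||% NA,
                             step_length = step_length_target %||% NA)),
            class = "gait_opt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_opt <- function(x, ...) {
  cat(sprintf("<gait_opt> subset '%s', best cost %.4f (stage %d)\n",
              x$subset, x$value, cost_stage(x$value)))
  invisible(x)
}

#' @export
tidy.gait_opt <- function(x, ...) x$cma$trace

#' @export
glance.gait_opt <- function(x, ...) {
  tibble::tibble(subset = x$subset, best = x$value,
                 stage = cost_stage(x$value), evals = x$cma$evals,
                 cadence_target = unname(x$targets["cadence"]),
                 step_length_target = unname(x$targets["step_length"]))
}
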