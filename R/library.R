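#' Basis-point gait library
#'
#' A gait library is a tibble with one row per learned gait: the 8 control
#' parameters plus `v_init` (see [control_names()]) and the achieved gait
#' descriptors `cadence` (steps/min), `step_length` (m) and `speed` (m/s),
#' measured over the standard window of a simulation with those
#' parameters.
#'
#' @param x A data frame with the required columns.
#' @return A validated `gait_library` tibble.
#' @export
gait_library <- function(x) {
  need <- c(control_names(), "cadence", "step_length", "speed")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing library columns: ", paste(missing, collapse = ", "))
  }
  x <- tibble::as_tibble(x)[, need]
  if (anyDuplicated(x[, control_names()])) {
    stop("duplicate control parameter sets in library")
  }
  class(x) <- c("gait_library", class(x))
  x
}

#' Read/write a gait library as CSV
#'
#' @param path File path.
#' @export
read_gait_library <- function(path) {
  gait_library(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_gait_library
#' @param lib A `gait_library`.
#' @export
write_gait_library <- function(lib, path) {
  utils::write.csv(as.data.frame(lib), path, row.names = FALSE)
  invisible(path)
}

#' Generalize to an unlearned gait by nearest-neighbor interpolation
#'
#' Selects the five basis points nearest to the target in the
#' cadence-step-length plane (each axis standardized by the library's
#' standard deviation, so the mixed units do not bias the distance) and
#' returns the convex combination of their control-parameter vectors with
#' normalized inverse-distance weights. A target that exactly matches a
#' basis point returns that row's parameters unchanged.
#'
#' @param cadence,step_length Target gait descriptors.
#' @param lib A `gait_library` with at least 5 rows.
#' @param k Number of neighbors (default 5).
#' @return Named control-parameter vector (9 values, including `v_init`)
#'   with attributes `weights` and `neighbors` (row indices).
#' @export
interpolate_gait <- function(cadence, step_length, lib, k = 5) {
  lib <- gait_library(lib)
  if (nrow(lib) < k) stop("library needs at least ", k, " basis points")
  s_cad <- stats::sd(lib$cadence)
  s_sl <- stats::sd(lib$step_length)
  if (!is.finite(s_cad) || s_cad == 0) s_cad <- 1
  if (!is.finite(s_sl) || s_sl == 0) s_sl <- 1
  d <- sqrt(((lib$cadence - cadence) / s_cad)^2 +
            ((lib$step_length - step_length) / s_sl)^2)
  exact <- which(d < 1e-12)
  if (length(exact)) {
    out <- unlist(lib[exact[1], control_names()])
    attr(out, "weights") <- setNames(1, exact[1])
    attr(out, "neighbors") <- exact[1]
    return(out)
  }
  nn <- order(d)[seq_len(k)]
  w <- 1 / d[nn]
  w <- w / sum(w)
  P <- as.matrix(lib[nn, control_names()])
  out <- setNames(drop(w %*% P), control_names())
  attr(out, "weights") <- setNames(w, nn)
  attr(out, "neighbors") <- nn
  out
}

#' Build a transition schedule
#'
#' An ordered set of control-parameter switches at fixed times. Entries
#' can be given directly as control parameters or as target gaits to be
#' interpolated from a library.
#'
#' @param targets A tibble with columns `cadence` and `step_length` (one
#'   row per dwell, the first defining the initial gait), or a tibble of
#'   control-parameter columns.
#' @param lib Library for interpolation (required for gait targets).
#' @param dwell Dwell time per gait (s, default 20).
#' @return A `transition_schedule` tibble: `switch_time` plus the 9
#'   control-parameter columns (strictly increasing switch times; the
#'   first row is the initial parameter set at time 0).
#' @export
transition_schedule <- function(targets, lib = NULL, dwell = 20) {
  targets <- tibble::as_tibble(targets)
  if (all(c("cadence", "step_length") %in% names(targets)) &&
      !all(control_names() %in% names(targets))) {
    stopifnot(!is.null(lib))
    ctl <- purrr::pmap(targets[, c("cadence", "step_length")],
                       function(cadence, step_length) {
                         tibble::as_tibble_row(
                           c(interpolate_gait(cadence, step_length, lib)))
                       })
    ctl <- dplyr::bind_rows(ctl)
    ctl$target_cadence <- targets$cadence
    ctl$target_step_length <- targets$step_length
  } else {
    ctl <- targets[, intersect(names(targets),
                               c(control_names(), "target_cadence",
                                 "target_step_length"))]
  }
  out <- dplyr::mutate(ctl,
                       switch_time = dwell * (dplyr::row_number() - 1),
                       .before = 1)
  class(out) <- c("transition_schedule", class(out))
  out
}

#' Walk through a schedule of real-time gait transitions
#'
#' The model starts with the first parameter set (whose `v_init` sets the
#' onset speed) and switches to each subsequent set at its switch time,
#' irrespective of the current state of the gait cycle. Only the 8
#' control parameters are switched; balance and spinal parameters are
#' never modified. Per-segment gait metrics are measured over the last
#' `window` seconds of each dwell.
#'
#' @param schedule From [transition_schedule()].
#' @param params Base `walker_params` (spinal/balance/sim settings).
#' @param model A `walker_model`.
#' @param dwell Dwell time per gait (s); the total simulated duration is
#'   `dwell * nrow(schedule)` unless the model falls.
#' @param window Metric window per segment (s).
#' @param log_muscles Forwarded to the simulator.
#' @return A `transition_walk`: the full `walker_sim` plus
#'   `segment_metrics` (one row per dwell with targets and achieved
#'   gait).
#' @export
run_transition_walk <- function(schedule, params, model = load_model(),
                                dwell = 20, window = 10,
                                log_muscles = FALSE) {
  sched <- tibble::as_tibble(schedule)
  n <- nrow(sched)
  stopifnot(n >= 1)
  first <- as.list(sched[1, control_names()])
  params <- set_control(params, unlist(first))
  duration <- dwell * n
  init <- walking_initial_state(model, params)
  ctl_mat <- as.matrix(sched[, control_names()])
  if (n > 1) {
    times <- dwell * seq_len(n - 1)
    raw <- wk_simulate(model_ptr(model), params, duration, init,
                       log_muscles, TRUE, times,
                       ctl_mat[-1, , drop = FALSE])
  } else {
    raw <- wk_simulate(model_ptr(model), params, duration, init,
                       log_muscles, TRUE)
  }
  sim <- as_walker_sim(raw, model, params, duration, log_muscles)
  seg <- purrr::map_dfr(seq_len(n), function(i) {
    t1 <- min(dwell * i, sim$t_end)
    t0 <- max(dwell * (i - 1), t1 - window)
    sub <- sim
    sub$t_end <- t1
    sub$heel_strikes <- sim$heel_strikes[sim$heel_strikes$time <= t1, ]
    m <- gait_metrics(sub, window = t1 - t0)
    m$segment <- i
    m$switch_time <- dwell * (i - 1)
    m$completed <- is.null(sim$fall) || sim$fall$time >= dwell * i
    m
  })
  if (all(c("target_cadence", "target_step_length") %in% names(sched))) {
    seg$target_cadence <- sched$target_cadence[seg$segment]
    seg$target_step_length <- sched$target_step_length[seg$segment]
  }
  structure(list(sim = sim, segment_metrics = seg, schedule = sched,
                 dwell = dwell),
            class = "transition_walk")
}

#' @export
print.transition_walk <- function(x, ...) {
  cat(sprintf("<transition_walk> %d segments, walked %.1f of %.1f s\n",
              nrow(x$schedule), x$sim$t_end, x$dwell * nrow(x$schedule)))
  invisible(x)
}

#' Random gait-transition experiment
#'
#' Starting from a given gait, a new target step length and cadence are
#' drawn every dwell from a uniform interval around the current values,
#' the control parameters are interpolated from the library, and the
#' switch is executed in real time. A transition succeeds if the model
#' survives the dwell. Repeated for each interval radius.
#'
#' @param start_cadence,start_step_length Starting gait (should be near a
#'   stable library point).
#' @param lib A `gait_library`.
#' @param params Base `walker_params`.
#' @param model A `walker_model`.
#' @param radii Interval radii; each unit is 1 step/min in cadence and
#'   1 cm in step length (default `c(1, 3, 5, 7.5, 10)`).
#' @param n_walks Walks per radius.
#' @param n_transitions Transitions per walk (dwell 20 s, so walk length
#'   is `20 * (n_transitions + 1)` s at most).
#' @param dwell Dwell per gait (s).
#' @param seed Integer seed for the target draws.
#' @return A tibble with one row per radius: `radius`, `n_transitions`,
#'   `n_success`, `success_rate`.
#' @export
random_transition_experiment <- function(start_cadence, start_step_length,
                                         lib, params, model = load_model(),
                                         radii = c(1, 3, 5, 7.5, 10),
                                         n_walks = 3, n_transitions = 5,
                                         dwell = 20, seed = 1) {
  set.seed(as.integer(seed))
  purrr::map_dfr(radii, function(r) {
    att <- 0L; succ <- 0L
    for (w in seq_len(n_walks)) {
      cad <- start_cadence; sl <- start_step_length
      tg <- tibble::tibble(cadence = cad, step_length = sl)
      for (k in seq_len(n_transitions)) {
        cad <- cad + runif(1, -r, r)
        sl <- sl + runif(1, -r, r) / 100   # radius unit: cm
        tg <- dplyr::add_row(tg, cadence = cad, step_length = sl)
      }
      tw <- run_transition_walk(transition_schedule(tg, lib, dwell),
                                params, model, dwell = dwell)
      done <- tw$segment_metrics$completed[-1]
      att <- att + length(done)
      succ <- succ + sum(done)
      # transitions after a fall were never attempted
      if (!is.null(tw$sim$fall)) {
        attempted <- sum(dwell * seq_len(n_transitions) < tw$sim$fall$time) + 1
        att <- att - (n_transitions - min(attempted, n_transitions))
      }
    }
    tibble::tibble(radius = r, n_transitions = att, n_success = succ,
                   success_rate = if (att > 0) succ / att else NA_real_)
  })
}

#' Principal component analysis of the control-parameter library
#'
#' PCA on the standardized (z-scored) 8-dimensional control-parameter
#' rows of a library (the initial speed is not a control parameter and is
#' excluded). The explained-variance fractions show how much of the
#' library's variability is captured per component.
#'
#' @param lib A `gait_library` (>= 2 rows).
#' @return A `library_pca` object: `explained` (fractions, sorted,
#'   summing to 1), `cumulative`, `rotation`, `sdev`.
#' @export
library_pca <- function(lib) {
  lib <- gait_library(lib)
  stopifnot(nrow(lib) >= 2)
  X <- as.matrix(lib[, setdiff(control_names(), "v_init")])
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(explained = expl, cumulative = cumsum(expl),
                 rotation = pc$rotation, sdev = pc$sdev,
                 n = nrow(lib)),
            class = "library_pca")
}

#' @export
print.library_pca <- function(x, ...) {
  cat("<library_pca> explained variance (%):",
      paste(sprintf("%.1f", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.library_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained),
                 explained = x$explained,
                 cumulative = x$cumulative)
}

#' @export
glance.library_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$explained),
                 first_two = x$cumulative[min(2, length(x$cumulative))],
                 first_four = x$cumulative[min(4, length(x$cumulative))],
                 n_gaits = x$n)
}
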