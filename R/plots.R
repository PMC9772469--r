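#' Plot a walking simulation
#'
#' Joint-angle trajectories of both legs with stance phases and ground
#' reaction forces.
#'
#' @param sim A `walker_sim`.
#' @return A ggplot object.
#' @export
plot_simulation <- function(sim) {
  st <- sim$states
  ang <- tidyr::pivot_longer(
    st[, c("time", "hipfl_l", "knee_l", "ankle_l",
           "hipfl_r", "knee_r", "ankle_r", "pitch", "roll")],
    -"time", names_to = "joint", values_to = "angle")
  ggplot2::ggplot(ang, ggplot2::aes(.data$time, .data$angle * 180 / pi,
                                    colour = .data$joint)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "angle [deg]", colour = NULL,
                  title = "Joint and trunk angles") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.walker_sim <- function(object, ...) plot_simulation(object)

#' Plot ground reaction forces
#'
#' @param sim A `walker_sim`.
#' @return A ggplot object.
#' @export
plot_grf <- function(sim) {
  g <- tidyr::pivot_longer(sim$grf[, c("time", "fz_left", "fz_right")],
                           -"time", names_to = "foot", values_to = "fz")
  ggplot2::ggplot(g, ggplot2::aes(.data$time, .data$fz,
                                  colour = .data$foot)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "vertical ground force [N]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a gait library in the cadence-step-length plane
#'
#' @param lib A `gait_library`.
#' @param targets Optional tibble of target gaits to overlay.
#' @return A ggplot object.
#' @export
plot_gait_library <- function(lib, targets = NULL) {
  p <- ggplot2::ggplot(lib, ggplot2::aes(.data$cadence, .data$step_length)) +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "cadence [steps/min]", y = "step length [m]",
                  title = "Basis-point library") +
    ggplot2::theme_minimal()
  if (!is.null(targets)) {
    p <- p + ggplot2::geom_point(data = targets, colour = "firebrick",
                                 shape = 4, size = 3)
  }
  p
}

#' @export
autoplot.gait_library <- function(object, ...) plot_gait_library(object)

#' Plot a transition walk
#'
#' Achieved cadence and step length per segment against their targets.
#'
#' @param tw A `transition_walk`.
#' @return A ggplot object.
#' @export
plot_transition_walk <- function(tw) {
  seg <- tw$segment_metrics
  long <- dplyr::bind_rows(
    tibble::tibble(segment = seg$segment, what = "cadence [steps/min]",
                   achieved = seg$cadence,
                   target = seg$target_cadence %||% NA),
    tibble::tibble(segment = seg$segment, what = "step length [m]",
                   achieved = seg$step_length,
                   target = seg$target_step_length %||% NA))
  ggplot2::ggplot(long, ggplot2::aes(.data$segment)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$target), colour = "firebrick",
                       na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$achieved), na.rm = TRUE) +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "segment", y = NULL,
                  title = "Gait transitions: target vs achieved") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.transition_walk <- function(object, ...) plot_transition_walk(object)

#' Plot explained variance of a library PCA
#'
#' @param pca A `library_pca`.
#' @return A ggplot object.
#' @export
plot_library_pca <- function(pca) {
  d <- tidy(pca)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, 100 * .data$explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$cumulative),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = 100 * .data$cumulative),
                        colour = "firebrick") +
    ggplot2::labs(x = "principal component", y = "variance explained [%]") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.library_pca <- function(object, ...) plot_library_pca(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
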