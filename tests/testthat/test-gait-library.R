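test_that("fixture libraries are deterministic and span the stated ranges", {
  l1 <- generate_fixture_library(15, seed = 3)
  l2 <- generate_fixture_library(15, seed = 3)
  expect_identical(l1, l2)
  l3 <- generate_fixture_library(15, seed = 4)
  expect_false(identical(l1, l3))
  expect_true(all(l1$cadence >= 85 & l1$cadence <= 140))
  expect_true(all(l1$step_length >= 0.53 & l1$step_length <= 0.97))
  expect_error(generate_fixture_library(3), "n >= 5")
})

test_that("interpolation returns exact matches unchanged", {
  lib <- generate_fixture_library(20, seed = 1)
  i <- 7
  ctl <- interpolate_gait(lib$cadence[i], lib$step_length[i], lib)
  expect_equal(unname(c(ctl)), unname(unlist(lib[i, control_names()])),
               tolerance = 1e-12)
})

test_that("interpolation weights are a convex combination", {
  lib <- generate_fixture_library(30, seed = 2)
  set.seed(11)
  for (i in 1:1000) {
    ctl <- interpolate_gait(runif(1, 85, 140), runif(1, 0.53, 0.97), lib)
    w <- attr(ctl, "weights")
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # componentwise inside the hull of the neighbors
    nb <- as.matrix(lib[attr(ctl, "neighbors"), control_names()])
    expect_true(all(c(ctl) >= apply(nb, 2, min) - 1e-12))
    expect_true(all(c(ctl) <= apply(nb, 2, max) + 1e-12))
  }
})

test_that("interpolation reproduces affine libraries at symmetric layouts", {
  # five basis points on a regular pentagon around the target: equal
  # distances give equal weights, and the centroid equals the target, so
  # inverse-distance interpolation must return the affine prediction
  cad0 <- 110; sl0 <- 0.75
  ang <- 2 * pi * (0:4) / 5
  lib0 <- generate_fixture_library(20, seed = 5, noise_sd = 0)
  s_cad <- sd(lib0$cadence); s_sl <- sd(lib0$step_length)
  cad <- cad0 + 8 * cos(ang) * s_cad / s_cad
  sl <- sl0 + 8 * sin(ang) * s_sl / s_cad   # same standardized radius
  # build an affine parameter map over (cadence, step length)
  A <- matrix(c(0.004, 0.15, -0.002, 0.3, 0.001, 0.2, 0.003, -0.1, 0.002,
                0.05, -0.003, 0.25, 0.001, 0.1, 0.004, 0.4, 0.005, 0.2),
              nrow = 2)
  affine <- function(c_, s_) {
    v <- c(0.4, 0.8, 0.3, 0.2, 0.1, 0.5, 0.1, 0.5, 1.0) +
      drop(c(c_ - 110, (s_ - 0.75) * 100) %*% A)
    setNames(v, control_names())
  }
  rows <- lapply(seq_along(cad), function(i) {
    c(affine(cad[i], sl[i]), cadence = cad[i], step_length = sl[i],
      speed = cad[i] * sl[i] / 60)
  })
  lib <- gait_library(dplyr::bind_rows(lapply(rows, tibble::as_tibble_row)))
  ctl <- interpolate_gait(cad0, sl0, lib)
  expect_lt(max(abs(c(ctl) - affine(cad0, sl0))), 1e-6)
})

test_that("library PCA explains rank and isotropy correctly", {
  # noise-free affine fixture: exactly 2 components carry all variance
  lib <- generate_fixture_library(40, seed = 6, noise_sd = 0)
  pca <- library_pca(lib)
  expect_gte(pca$cumulative[2], 1 - 1e-9)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_equal(sum(pca$explained), 1, tolerance = 1e-12)

  # isotropic synthetic parameters: each of 8 components near 1/8
  set.seed(8)
  n <- 4000
  X <- matrix(rnorm(n * 8), n, 8)
  iso <- tibble::as_tibble(setNames(as.data.frame(X),
                                    setdiff(control_names(), "v_init")))
  iso$v_init <- 1.2
  iso$cadence <- seq_len(n); iso$step_length <- runif(n); iso$speed <- 1
  pca2 <- library_pca(gait_library(iso))
  expect_true(all(abs(pca2$explained - 1 / 8) < 0.02))
})

test_that("library round-trips through CSV", {
  lib <- generate_fixture_library(12, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_gait_library(lib, f)
  lib2 <- read_gait_library(f)
  expect_equal(as.data.frame(lib), as.data.frame(lib2), tolerance = 1e-12)
  unlink(f)
})

test_that("a single-entry schedule reproduces a plain simulation", {
  p <- test_params
  sched <- transition_schedule(
    tibble::as_tibble_row(c(control_set(p))), dwell = 2)
  tw <- run_transition_walk(sched, p, test_model, dwell = 2,
                            log_muscles = FALSE)
  sim <- run_simulation(p, test_model, duration = 2, log_muscles = FALSE)
  expect_identical(tw$sim$states, sim$states)
  expect_identical(tw$sim$heel_strikes, sim$heel_strikes)
})

test_that("switching to identical parameters does not perturb the walk", {
  p <- test_params
  ctl <- tibble::as_tibble_row(c(control_set(p)))
  sched <- transition_schedule(dplyr::bind_rows(ctl, ctl, ctl), dwell = 0.8)
  tw <- run_transition_walk(sched, p, test_model, dwell = 0.8,
                            log_muscles = FALSE)
  sim <- run_simulation(p, test_model, duration = 2.4, log_muscles = FALSE)
  expect_identical(tw$sim$states, sim$states)
})

test_that("transition schedules never touch spinal or balance parameters", {
  lib <- generate_fixture_library(20, seed = 1)
  sched <- transition_schedule(
    tibble::tibble(cadence = c(100, 110), step_length = c(0.7, 0.75)),
    lib, dwell = 1)
  # the schedule carries only control-parameter columns (plus targets/time)
  expect_true(all(setdiff(names(sched),
                          c("switch_time", "target_cadence",
                            "target_step_length")) %in% control_names()))
  expect_true(all(diff(sched$switch_time) > 0))
})

test_that("interpolated transitions run and report per-segment metrics", {
  lib <- generate_fixture_library(20, seed = 1)
  sched <- transition_schedule(
    tibble::tibble(cadence = c(105, 115), step_length = c(0.7, 0.72)),
    lib, dwell = 1.5)
  tw <- run_transition_walk(sched, test_params, test_model, dwell = 1.5,
                            window = 1.0, log_muscles = FALSE)
  expect_equal(nrow(tw$segment_metrics), 2)
  expect_true(all(c("target_cadence", "completed") %in%
                  names(tw$segment_metrics)))
})

test_that("the random transition experiment is seeded and tabulated", {
  lib <- generate_fixture_library(20, seed = 1)
  r1 <- random_transition_experiment(110, 0.7, lib, test_params, test_model,
                                     radii = c(0, 5), n_walks = 1,
                                     n_transitions = 1, dwell = 0.6, seed = 5)
  r2 <- random_transition_experiment(110, 0.7, lib, test_params, test_model,
                                     radii = c(0, 5), n_walks = 1,
                                     n_transitions = 1, dwell = 0.6, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$radius, c(0, 5))
  expect_true(all(r1$n_success <= r1$n_transitions))
})
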