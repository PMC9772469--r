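test_that("minimal jerk holds a reached goal and satisfies rest-to-rest identities", {
  # already at the goal: constant trajectory, zero acceleration
  tr <- minimal_jerk(1, 0, 0, 1, 0.5, seq(0, 0.5, by = 0.01))
  expect_true(all(abs(tr$x - 1) < 1e-12))
  expect_true(all(abs(tr$a) < 1e-9))
  # rest-to-rest 0 -> 1 over T: midpoint 0.5, peak velocity 1.875/T at T/2
  for (T in c(0.3, 1, 2.5)) {
    tr <- minimal_jerk(0, 0, 0, 1, T, seq(0, T, length.out = 2001))
    expect_equal(tr$x[1001], 0.5, tolerance = 1e-9)
    expect_equal(max(tr$v), 1.875 / T, tolerance = 1e-6)
    expect_equal(which.max(tr$v), 1001)
    # boundary conditions met exactly
    expect_equal(tr$x[2001], 1, tolerance = 1e-9)
    expect_equal(tr$v[2001], 0, tolerance = 1e-9)
    expect_equal(tr$a[2001], 0, tolerance = 1e-6)
  }
})

test_that("the quintic minimizes the jerk integral among same-boundary rivals", {
  set.seed(21)
  T <- 0.8
  tt <- seq(0, T, length.out = 4001)
  dt <- tt[2] - tt[1]
  jerk_integral <- function(x) {
    j <- diff(x, differences = 3) / dt^3
    sum(j^2) * dt
  }
  base <- minimal_jerk(0.2, -0.5, 1, 1, T, tt)
  J0 <- jerk_integral(base$x)
  for (i in 1:100) {
    # rival: quintic plus a random bump vanishing (with 2 derivatives) at ends
    w <- (tt / T)^3 * (1 - tt / T)^3
    rival <- base$x + runif(1, -2, 2) * w * sin(runif(1, 1, 6) * pi * tt / T)
    expect_gte(jerk_integral(rival), J0 * (1 - 1e-6))
  }
})

test_that("swing targets apply the balance feedback law", {
  p <- test_params
  p$balance$cd_early_sag <- 0.3; p$balance$cv_early_sag <- 0.1
  p$control$theta_hipfl_early <- 0.6
  tg <- swing_targets(p, d_sag = 0.1, v_sag = 0.2, d_fro = 0, v_fro = 0,
                      phi_pitch = 0.05, phi_roll = 0, "early", "left")
  # 0.6 + 0.3*0.1 + 0.1*0.2 - 0.05 = 0.6
  expect_equal(unname(tg["hipfl"]), 0.6)
  expect_equal(unname(tg["knee"]), p$control$theta_knee_early)
  expect_equal(unname(tg["ankle"]), p$control$theta_ankle)
  # no feedback: nominal target
  tg0 <- swing_targets(p, 0, 0, 0, 0, 0, 0, "early", "left")
  expect_equal(unname(tg0["hipfl"]), 0.6)
  # forward trunk offset raises the hip flexion target (positive gains)
  tgf <- swing_targets(p, 0.2, 0, 0, 0, 0, 0, "early", "left")
  expect_gt(tgf["hipfl"], tg0["hipfl"])
  # frontal plane mirrors between legs
  tl <- swing_targets(p, 0, 0, 0.1, 0, 0, 0, "early", "left")
  tr <- swing_targets(p, 0, 0, 0.1, 0, 0, 0, "early", "right")
  expect_equal(unname(tl["hipab"]), -unname(tr["hipab"]))
})

test_that("propulsion plan satisfies its constraints to high precision", {
  set.seed(13)
  for (rep in 1:20) {
    q <- random_config()
    st <- list(q = q, qd = numeric(14))
    side <- sample(c("left", "right"), 1)
    J <- trunk_com_jacobian(test_model, st, side)
    Mc <- stance_chain_mass(test_model, st, side)
    a_x <- runif(1, 0.1, 2)
    pl <- propulsion_plan(J, Mc, a_x)
    A <- rbind(J[1, ], J[6, ], Mc["ball", ], Mc["hipab", ])
    b <- c(a_x, 0, 0, 0)
    expect_lt(pl$residual, 1e-8)
    expect_lt(max(abs(A %*% pl$qdd - b)), 1e-8)
    # ball-hinge torque is zero by construction
    expect_lt(abs(pl$tau["ball"]), 1e-8)
    expect_lt(abs(pl$tau["hipab"]), 1e-8)
    # minimum-norm among solutions: matches the explicit least-squares oracle
    qdd_ls <- oracle_pinv(A) %*% b
    expect_lt(max(abs(pl$qdd - qdd_ls)), 1e-7)
    # linearity
    pl2 <- propulsion_plan(J, Mc, 2 * a_x)
    expect_lt(max(abs(pl2$qdd - 2 * pl$qdd)), 1e-7)
  }
})

test_that("zero desired acceleration gives the zero minimum-norm solution", {
  q <- test_model$q0
  q[5] <- 0.1
  q[c(8, 9, 10)] <- c(0.25, 0.3, 0.1)  # generic single-stance posture
  st <- list(q = q, qd = numeric(14))
  J <- trunk_com_jacobian(test_model, st, "left")
  Mc <- stance_chain_mass(test_model, st, "left")
  pl <- propulsion_plan(J, Mc, 0)
  expect_equal(unname(pl$qdd), numeric(5))
})

test_that("an unreachable propulsion demand is solved least-squares with a warning", {
  # forward translation structurally impossible: j_x identically zero
  J <- matrix(0, 6, 5)
  J[6, ] <- c(1, 0, -1, 1, 1)
  Mc <- diag(5) + 0.1
  dimnames(Mc) <- list(c("hipfl", "hipab", "knee", "ankle", "ball"),
                       c("hipfl", "hipab", "knee", "ankle", "ball"))
  expect_warning(pl <- propulsion_plan(J, Mc, 0.5), "unreachable")
  expect_true(all(is.finite(pl$qdd)))
  expect_gt(pl$residual, 1e-8)
})

test_that("the propulsion plan meets its constraints on synthetic full-rank systems", {
  set.seed(17)
  for (rep in 1:20) {
    J <- matrix(rnorm(30), 6, 5)
    Mc <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
    dimnames(Mc) <- list(c("hipfl", "hipab", "knee", "ankle", "ball"),
                         c("hipfl", "hipab", "knee", "ankle", "ball"))
    pl <- propulsion_plan(J, Mc, 1)
    A <- rbind(J[1, ], J[6, ], Mc["ball", ], Mc["hipab", ])
    expect_lt(max(abs(A %*% pl$qdd - c(1, 0, 0, 0))), 1e-10)
    qdd_ls <- oracle_pinv(A) %*% c(1, 0, 0, 0)
    expect_lt(max(abs(pl$qdd - qdd_ls)), 1e-9)
  }
})

test_that("the gait FSM follows the legal transition graph", {
  opts <- list(early_share = 0.5, min_stance = 0.2, min_swing_frac = 0.25,
               unload_frac = 0.25, pushoff_timeout = 0.15,
               body_weight = 785)
  ph <- list(left = list(phase = "stance", phase_t = 1, contra_td = NA),
             right = list(phase = "stance", phase_t = 0.05, contra_td = NA))
  # right just touched down and is loaded; left unloads -> left swings
  ph2 <- ph
  for (i in 1:5) {
    ph2 <- fsm_step(ph2, c(left = TRUE, right = TRUE),
                    c(left = 100, right = 700), t = 1 + i * 0.001,
                    t_swing = 0.5, dt = 0.001, opts)
  }
  expect_equal(ph2$left$phase, "early_swing")
  expect_equal(ph2$right$phase, "stance")
  # early -> late at the configured share of the swing time
  ph3 <- ph2
  t <- 1.005
  repeat {
    ph3 <- fsm_step(ph3, c(left = FALSE, right = TRUE),
                    c(left = 0, right = 785), t, 0.5, 0.001, opts)
    t <- t + 0.001
    if (ph3$left$phase != "early_swing") break
  }
  expect_equal(ph3$left$phase, "late_swing")
  expect_equal(ph3$left$phase_t, 0.25, tolerance = 0.01)
  # touchdown in late swing -> stance
  ph4 <- fsm_step(ph3, c(left = TRUE, right = TRUE),
                  c(left = 400, right = 400), t, 0.5, 0.001, opts)
  expect_equal(ph4$left$phase, "stance")
})

test_that("simulated walking produces only legal transitions and alternating strikes", {
  sim <- run_simulation(test_params, test_model, duration = 3,
                        log_muscles = FALSE)
  legal <- list(stance = "early_swing", early_swing = c("late_swing", "stance"),
                late_swing = "stance")
  tr <- sim$transitions
  for (i in seq_len(nrow(tr))) {
    expect_true(tr$to[i] %in% legal[[tr$from[i]]])
  }
  expect_true(all(diff(sim$heel_strikes$time) >= 0))
})
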