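test_that("stance inverse dynamics is the mass-matrix map", {
  M <- diag(c(2, 1, 1, 1, 1))
  dimnames(M) <- list(c("hipfl", "hipab", "knee", "ankle", "ball"),
                      c("hipfl", "hipab", "knee", "ankle", "ball"))
  expect_equal(inverse_dynamics_stance(c(1, 0, 0, 0, 0), M),
               c(hipfl = 2, hipab = 0, knee = 0, ankle = 0, ball = 0))
  expect_equal(unname(inverse_dynamics_stance(numeric(5), M)), numeric(5))
})

test_that("swing inverse dynamics matches the gravity oracle for a hanging leg", {
  q <- numeric(14); q[3] <- 0.959; q[8] <- 0.3; q[9] <- 0.5; q[10] <- 0.1
  st <- list(q = q, qd = numeric(14))
  tau <- inverse_dynamics_swing(test_model, st, "left", numeric(4),
                                base_motion = FALSE)
  g <- oracle_gravity(test_model$cfg, q)
  # holding the posture requires exactly the negative gravity torques
  expect_equal(unname(tau[c("hipab", "hipfl", "knee", "ankle")]),
               -g[7:10], tolerance = 1e-6)
})

test_that("swing inverse dynamics reduces to M qdd without gravity terms", {
  # zero-gravity equivalence: tau(qdd) - tau(0) is the inertial part, and
  # must match the corresponding block of the full mass matrix
  q <- random_config()
  st <- list(q = q, qd = numeric(14))
  qdd <- c(2, -1, 1.5, 0.5)   # hipfl, hipab, knee, ankle
  tau <- inverse_dynamics_swing(test_model, st, "left", qdd, FALSE)
  tau0 <- inverse_dynamics_swing(test_model, st, "left", numeric(4), FALSE)
  M <- mass_matrix(test_model, q)
  blk <- M[7:10, 7:10]  # hipab, hipfl, knee, ankle
  qdd_chain <- c(qdd[2], qdd[1], qdd[3], qdd[4])
  tau_chain <- drop(blk %*% qdd_chain)
  # subtracting the zero-acceleration torques removes the gravity terms
  expect_equal(unname((tau - tau0)[c("hipab", "hipfl", "knee", "ankle")]),
               unname(tau_chain), tolerance = 1e-8)
})

test_that("swing torques reproduce the desired accelerations in forward dynamics", {
  # forward/inverse round trip on the full model with the base held at the
  # current state (swing chain isolated, zero base velocity)
  q <- numeric(14); q[3] <- 1.2; q[8] <- 0.4; q[9] <- 0.7; q[10] <- 0.05
  st <- list(q = q, qd = numeric(14))
  qdd_des <- c(3, -0.5, 2, 1)   # hipfl, hipab, knee, ankle
  tau <- inverse_dynamics_swing(test_model, st, "left", qdd_des, FALSE)
  M <- mass_matrix(test_model, q)
  g <- oracle_gravity(test_model$cfg, q)
  Q <- numeric(14)
  Q[7:10] <- tau[c("hipab", "hipfl", "knee", "ankle")]
  # base locked: solve only the swing block with the base constrained
  qdd <- solve(M[7:10, 7:10], (Q + g)[7:10])
  expect_equal(unname(qdd), c(qdd_des[2], qdd_des[1], qdd_des[3], qdd_des[4]),
               tolerance = 1e-6)
})

test_that("force distribution matches closed forms on two-muscle toys", {
  # two agonists, no sign conflict: minimum-norm row solution
  R <- matrix(c(0.05, 0.10), 1, 2)
  F <- distribute_forces(1, R)
  expect_equal(as.numeric(F), c(4, 8), tolerance = 1e-9)
  expect_lt(attr(F, "residual"), 1e-10)
  # agonist/antagonist: antagonist pinned at its bound
  R2 <- matrix(c(0.05, -0.05), 1, 2)
  F2 <- distribute_forces(1, R2)
  expect_equal(as.numeric(F2), c(20, 0), tolerance = 1e-9)
  # zero torque: zero force (unique minimum)
  expect_equal(as.numeric(distribute_forces(0, R)), c(0, 0))
})

test_that("force distribution matches the brute-force oracle on random toys", {
  set.seed(31)
  for (rep in 1:200) {
    m <- sample(1:2, 1)
    k <- sample(2:3, 1)
    R <- matrix(runif(m * k, -0.1, 0.1), m, k)
    F_opt <- oracle_qp(R, runif(m, -1, 1) -> tau)
    if (is.null(F_opt)) next  # infeasible for nonnegative forces
    F <- suppressWarnings(distribute_forces(tau, R))
    expect_lt(max(abs(F - F_opt)), 1e-6)
    expect_lt(max(abs(R %*% F - tau)), 1e-6)
    expect_true(all(F >= -1e-12))
  }
})

test_that("bounded force distribution respects capacity bounds", {
  R <- matrix(c(0.05, 0.10), 1, 2)
  ub <- c(3, 100)
  F <- distribute_forces(1, R, upper = ub)
  expect_true(all(F <= ub + 1e-9))
  expect_lt(attr(F, "residual"), 1e-9)
  # with the first muscle capped, the second takes over the remainder
  expect_equal(F[1], 3, tolerance = 1e-6)
  expect_equal(F[2], (1 - 3 * 0.05) / 0.10, tolerance = 1e-6)
})

test_that("infeasible torque demands fall back to clamped least squares", {
  R <- matrix(c(0.05, 0.04), 1, 2)   # both positive arms
  expect_warning(F <- distribute_forces(-1, R), "infeasible")
  expect_true(all(F >= 0))
})

test_that("Hill inversion recovers stimulation from force", {
  expect_equal(invert_muscle(1200, 3000, 0.8, 1.0), 0.5)
  expect_equal(invert_muscle(0, 3000, 0.8, 1.0), 0)
  # clamp at capacity
  expect_equal(invert_muscle(5000, 3000, 0.8, 1.0), 1)
  # guard region: capped at 1 with a warning
  expect_warning(s <- invert_muscle(100, 3000, 0.05, 0.5), "unproducible")
  expect_equal(s, 1)
})

test_that("reflex inversion follows the threshold-shift formula", {
  expect_equal(invert_reflex(0.2, 1, 2, 0.5), 0.1)
})

test_that("the command chain tracks a minimal-jerk swing on the isolated chain", {
  # no delays, base locked: hip flexion and knee follow a planned
  # minimal-jerk movement with small end-point error through
  # ID -> force distribution -> Hill inversion -> muscle dynamics
  q <- numeric(14); q[3] <- 2.0; q[8] <- 0.2; q[9] <- 0.5; q[10] <- 0.0
  dt <- 1e-4
  mdl <- test_model
  mus <- lapply(mdl$cfg$muscles, function(mc) {
    muscle_tendon_unit(mc$fmax, mc$lopt, mc$lslack, mc$vmax_rel,
                       mc$tau_act, mc$tau_deact)
  })
  names(mus) <- vapply(mdl$cfg$muscles, `[[`, "", "name")
  stq <- list(q = q, qd = numeric(14))
  lms <- muscle_lengths(mdl, stq)[1:10]
  mst <- lapply(seq_along(mus), function(i) init_muscle(mus[[i]], lms[i]))
  hill <- mdl$cfg$hill
  T_mov <- 0.7
  T_tot <- 1.0   # movement + settling under a position-hold plan
  goal <- c(hipfl = 0.5, knee = 0.7)
  a_pl <- c(0, 0)
  a_des_prev <- rep(0, 10)
  S <- rep(0, 10)
  t <- 0
  for (step in 1:(T_tot / dt)) {
    if (step %% 10 == 1) {   # control tick at 1 kHz, replanned from the
      T_rem <- max(T_mov - t, 0.05)   # current (undelayed) sensed state
      a_hip <- minimal_jerk(stq$q[8], stq$qd[8], a_pl[1], goal["hipfl"],
                            T_rem, 0.02)$a
      a_kne <- minimal_jerk(stq$q[9], stq$qd[9], a_pl[2], goal["knee"],
                            T_rem, 0.02)$a
      a_pl <- c(a_hip, a_kne)
      tau_d <- inverse_dynamics_swing(mdl, stq, "left",
                                      c(a_hip, 0, a_kne, 0), FALSE)
      Rm <- moment_arm_matrix(mdl, stq)[1:4, 1:10]
      Rm <- Rm[c("hipfl_l", "hipab_l", "knee_l", "ankle_l"), ]
      caps <- vapply(seq_along(mus), function(i) {
        ch <- muscle_characteristics(mst[[i]]$lce, mst[[i]]$vce, mus[[i]], hill)
        max(mus[[i]]$fmax * ch["f_l"] * ch["f_v"], 0.05 * mus[[i]]$fmax)
      }, numeric(1))
      Fd <- suppressWarnings(
        distribute_forces(tau_d[c("hipfl", "hipab", "knee", "ankle")],
                          Rm, upper = caps))
      a_des <- pmin(pmax(Fd / caps, 0), 1)
      # invert the first-order activation dynamics (lead compensation)
      adot <- (a_des - a_des_prev) / 1e-3
      tau_a <- ifelse(adot >= 0, vapply(mus, `[[`, 0, "tau_act"),
                      vapply(mus, `[[`, 0, "tau_deact"))
      S <- pmin(pmax(a_des + tau_a * adot, 0), 1)
      a_des_prev <- a_des
    }
    lms <- muscle_lengths(mdl, stq)[1:10]
    tau8 <- numeric(8)
    Rnow <- moment_arm_matrix(mdl, stq)[, 1:10]
    for (i in seq_along(mus)) {
      mst[[i]] <- step_muscle(mus[[i]], mst[[i]], S[i], lms[i], dt, hill)
      tau8 <- tau8 + Rnow[, i] * mst[[i]]$F
    }
    # base locked: integrate only the left-leg block
    M <- mass_matrix(mdl, stq$q)[7:10, 7:10]
    g <- inverse_dynamics_swing(mdl, stq, "left", numeric(4), FALSE)
    rhs <- tau8[1:4] - g[c("hipab", "hipfl", "knee", "ankle")]
    qdd <- solve(M, rhs)
    stq$qd[7:10] <- stq$qd[7:10] + dt * qdd
    stq$q[7:10] <- stq$q[7:10] + dt * stq$qd[7:10]
    t <- t + dt
  }
  err_deg <- abs(c(stq$q[8], stq$q[9]) - goal) * 180 / pi
  expect_lt(max(err_deg), 2)
})
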