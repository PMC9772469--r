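test_that("mass matrix is symmetric positive definite at random configurations", {
  set.seed(42)
  for (i in 1:100) {
    M <- mass_matrix(test_model, random_config())
    expect_lt(max(abs(M - t(M))), 1e-9)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("mass matrix matches the kinetic-energy oracle", {
  set.seed(7)
  for (i in 1:3) {
    q <- random_config()
    M <- mass_matrix(test_model, q)
    Mo <- oracle_mass_matrix(test_model$cfg, q)
    expect_lt(max(abs(M - Mo)) / max(abs(Mo)), 1e-6)
  }
})

test_that("forward dynamics solves the independently assembled equation of motion", {
  set.seed(11)
  for (i in 1:3) {
    q <- random_config()
    tau8 <- runif(8, -40, 40)
    # zero velocity removes Coriolis terms; gravity from the potential oracle
    qdd <- forward_dynamics(test_model, list(q = q, qd = numeric(14)),
                            tau8, contact = FALSE)
    Mo <- oracle_mass_matrix(test_model$cfg, q)
    g <- oracle_gravity(test_model$cfg, q)
    Q <- c(numeric(6), tau8) + g
    expect_lt(max(abs(qdd - solve(Mo, Q))), 1e-4)
  }
})

test_that("power balance holds along a driven trajectory", {
  # dE/dt equals the power injected by the actuated joints
  q <- random_config(); qd <- random_velocity() * 0.3
  tau8 <- runif(8, -20, 20)
  dt <- 1e-4
  st <- list(q = q, qd = qd)
  E0 <- mechanical_energy(test_model, st)
  W <- 0
  for (i in 1:200) {
    qdd <- forward_dynamics(test_model, st, tau8, contact = FALSE)
    W <- W + sum(tau8 * st$qd[7:14]) * dt
    st$qd <- st$qd + dt * qdd
    st$q <- st$q + dt * st$qd
  }
  E1 <- mechanical_energy(test_model, st)
  expect_lt(abs((E1 - E0) - W) / max(abs(E1 - E0), 1), 5e-3)
})

test_that("passive airborne skeleton conserves energy to <0.1% over 5 s", {
  q <- numeric(14); q[3] <- 3
  q[7:14] <- c(0.1, 0.3, 0.5, 0.1, -0.1, 0.4, 0.2, 0)
  qd <- numeric(14); qd[4:6] <- c(0.2, -0.1, 0.3)
  qd[7:14] <- c(0.5, -0.3, 0.2, 0.1, 0.4, -0.2, 0.1, 0.3)
  res <- gaitplanr:::wk_passive_sim(model_ptr(test_model), q, qd,
                                    1e-4, 50000, FALSE)
  E <- res$energy
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-3)
})

test_that("trunk CoM Jacobian matches rigid-rotation finite differences", {
  set.seed(3)
  for (rep in 1:20) {
    q <- random_config()
    st <- list(q = q, qd = numeric(14))
    side <- sample(c("left", "right"), 1)
    J <- trunk_com_jacobian(test_model, st, side)
    # geometry of the chain from the package's own kinematics
    f <- gaitplanr:::wk_fk(model_ptr(test_model), q, numeric(14))
    ch <- gaitplanr:::wk_chain(model_ptr(test_model), q, numeric(14),
                               if (side == "left") 0L else 1L)
    c_tr <- f$trunk_com
    base <- if (side == "left") 0 else 4
    # single-joint motion with the foot fixed is an exact rigid rotation of
    # the proximal assembly about the joint; differentiate that rotation
    jidx <- list(hipfl = 8 + base, hipab = 7 + base, knee = 9 + base,
                 ankle = 10 + base)
    h <- 1e-7
    for (k in seq_along(jidx)) {
      jq <- jidx[[k]]
      p_j <- f$p_joint[jq, ]
      a_j <- -f$axis[jq, ]     # proximal side rotates by minus the joint axis
      cp <- p_j + rot_axis(a_j, h) %*% (c_tr - p_j)
      cm <- p_j + rot_axis(a_j, -h) %*% (c_tr - p_j)
      v_fd <- (cp - cm) / (2 * h)
      expect_lt(max(abs(v_fd - J[1:3, names(jidx)[k]])), 1e-6)
      expect_lt(max(abs(a_j - J[4:6, names(jidx)[k]])), 1e-9)
    }
    # ball hinge: rotation about the foot's transverse axis at the ball point
    a_b <- f$p_joint[10 + base, ] # ankle pos (only used to check finiteness)
    expect_true(all(is.finite(J)))
    # zero joint rates give zero trunk velocity
    expect_equal(unname(drop(J %*% numeric(5))), numeric(6))
  }
})

test_that("straight-leg ankle rotation moves the trunk CoM at omega x r", {
  q <- numeric(14); q[3] <- 0.959
  st <- list(q = q, qd = numeric(14))
  J <- trunk_com_jacobian(test_model, st, "left")
  f <- gaitplanr:::wk_fk(model_ptr(test_model), q, numeric(14))
  # perpendicular distance from the trunk CoM to the ankle axis (the axis
  # is transverse, so the lateral hip offset does not contribute)
  d <- f$trunk_com - f$p_joint[10, ]
  r <- sqrt(d[1]^2 + d[3]^2)
  v <- J[1:3, "ankle"]
  expect_equal(unname(sqrt(sum(v^2))), r, tolerance = 1e-9)
})

test_that("contact model: no forces above ground, damping increases normal force", {
  q <- numeric(14); q[3] <- 2
  cf <- contact_model(test_model, list(q = q, qd = numeric(14)))
  expect_true(all(!cf$contact))
  expect_true(all(cf$fz == 0))

  # same penetration, at rest vs moving downward
  q[3] <- 0.9585   # slight penetration
  f_rest <- contact_model(test_model, list(q = q, qd = numeric(14)))
  qd <- numeric(14); qd[3] <- -0.2
  f_down <- contact_model(test_model, list(q = q, qd = qd))
  expect_true(all(f_down$fz[f_down$contact] > f_rest$fz[f_rest$contact]))
  expect_true(all(f_rest$fz >= 0))
})

test_that("standing skeleton held by joint servos supports body weight within 1%", {
  # high-gain joint servos hold the reference posture; after transients the
  # total vertical ground force balances the weight
  st <- standing_state(test_model)
  dt <- 1e-4
  kp <- 600; kd <- 30
  q_ref <- st$q[7:14]
  fz_hist <- numeric(0)
  for (i in 1:15000) {
    tau8 <- kp * (q_ref - st$q[7:14]) - kd * st$qd[7:14]
    qdd <- forward_dynamics(test_model, st, tau8, contact = TRUE)
    st$qd <- st$qd + dt * qdd
    st$q <- st$q + dt * st$qd
    if (i > 10000 && i %% 100 == 0) {
      cf <- contact_model(test_model, st)
      fz_hist <- c(fz_hist, sum(attr(cf, "fz")))
    }
  }
  W <- test_model$info$total_mass * test_model$cfg$gravity
  expect_lt(abs(mean(fz_hist) - W) / W, 0.01)
})

test_that("contact impulse equals momentum change in a drop test", {
  # ballistic drop onto the ground: Newton's third law couples the contact
  # impulse on the feet to the momentum change of the whole system
  q <- numeric(14); q[3] <- 1.05  # slightly airborne
  qd <- numeric(14)
  n <- 8000; dt <- 1e-4
  res <- gaitplanr:::wk_passive_sim(model_ptr(test_model), q, qd, dt, n, TRUE)
  mass <- test_model$info$total_mass
  g <- test_model$cfg$gravity
  p0 <- c(0, 0, 0)
  grav_imp <- c(0, 0, -mass * g * n * dt)
  expect_lt(max(abs((res$impulse + grav_imp) - (res$momentum - p0))), 0.5)
})

test_that("forward dynamics rejects non-finite input", {
  st <- standing_state(test_model)
  st$q[3] <- NaN
  expect_error(forward_dynamics(test_model, st), "non-finite")
})
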