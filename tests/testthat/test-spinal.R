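test_that("stretch reflex evaluates the threshold law and rectifies", {
  # worked example: K_l (l + u) + K_v (v + udot) - h = 2*0.6 + 0 - 1 = 0.2
  expect_equal(stretch_reflex(0.5, 0, 0.1, 0, K_l = 2, K_v = 0.1, h = 1), 0.2)
  # below threshold: zero
  expect_equal(stretch_reflex(0.4, 0, 0, 0, K_l = 2, K_v = 0.1, h = 1), 0)
  expect_equal(stretch_reflex(0.2, -1, 0, 0, K_l = 1, K_v = 0.5, h = 0.1), 0)
})

test_that("stretch reflex and its inversion are exact inverses in the static case", {
  set.seed(9)
  for (i in 1:1000) {
    S <- runif(1)
    h <- runif(1, 0, 2)
    K_l <- runif(1, 0.5, 5)
    lce <- runif(1, 0.2, 1.5)
    u <- invert_reflex(S, h, K_l, lce)
    expect_equal(stretch_reflex(lce, 0, u, 0, K_l, 0.3, h), S,
                 tolerance = 1e-12)
  }
  # S = 0 places the muscle exactly at threshold
  u0 <- invert_reflex(0, h = 1, K_l = 2, lce = 0.5)
  expect_equal(2 * (0.5 + u0), 1)
})

test_that("trunk-balance stimulation follows the force-modulated spring law", {
  # worked example: c * F * error = 1e-4 * 2000 * 0.1 = 0.02
  s <- fmch_stimulation(2000, 0.18, 0.08, c_ham = 1e-4, c_rf = 1e-4)
  expect_equal(unname(s["HAM"]), 0.02)
  expect_equal(unname(s["RF"]), 0)
  # zero error: both sides silent
  s0 <- fmch_stimulation(2000, 0.08, 0.08, 1e-4, 1e-4)
  expect_equal(unname(s0), c(0, 0))
  # linear in the leg force
  s2 <- fmch_stimulation(4000, 0.18, 0.08, 1e-4, 1e-4)
  expect_equal(unname(s2["HAM"]), 2 * unname(s["HAM"]))
  # extension error drives the flexor side
  sx <- fmch_stimulation(2000, -0.02, 0.08, 1e-4, 2e-4)
  expect_equal(unname(sx["HAM"]), 0)
  expect_equal(unname(sx["RF"]), 2e-4 * 2000 * 0.1)
})

test_that("leg force estimate divides the torque combination by the lever arm", {
  expect_equal(leg_force_estimate(3000, 0.04, 2500, 0.05),
               (3000 * 0.04 + 2500 * 0.05) / 0.032)
  expect_equal(leg_force_estimate(3000, 0.04, 2500, 0.05), 7656.25)
  expect_equal(leg_force_estimate(0, 0.04, 0, 0.05), 0)
  # linear in each force input
  expect_equal(leg_force_estimate(6000, 0.04, 2500, 0.05) -
               leg_force_estimate(3000, 0.04, 2500, 0.05),
               3000 * 0.04 / 0.032)
})

test_that("compliant-leg feedback is positive force feedback, stance only", {
  expect_equal(compliant_leg_stimulation(4000, 2e-4, stance = TRUE), 0.8)
  expect_equal(compliant_leg_stimulation(4000, 2e-4, stance = FALSE), 0)
  # closed loop with loop gain > 1 saturates at the ceiling
  mtu <- muscle_tendon_unit(4000, 0.04, 0.26, vmax_rel = 6)
  G <- 1.2 / 4000 * 4   # G * F_max > 1
  lm <- 0.26 * 1.03 + 0.04
  st <- init_muscle(mtu, 0.30)
  S <- 0.05
  for (i in 1:30000) {
    st <- step_muscle(mtu, st, S, lm, 1e-4)
    S <- combine_stimulations(0, S_CL = compliant_leg_stimulation(st$F, G))
  }
  expect_equal(S, 1)
})

test_that("knee-overextension guard activates near full extension while extending", {
  expect_equal(knee_overextension_stimulation(30 * pi / 180, -1, 0.12, 2, 0.3), 0)
  expect_gt(knee_overextension_stimulation(2 * pi / 180, -0.5, 0.12, 2, 0.3), 0)
  # silent when flexing, even inside the margin
  expect_equal(knee_overextension_stimulation(0.02, 0.5, 0.12, 2, 0.3), 0)
  # non-decreasing in extension velocity at fixed angle
  v <- seq(0, 3, by = 0.25)
  s <- knee_overextension_stimulation(0.05, -v, 0.12, 2, 0.3)
  expect_true(all(diff(s) >= 0))
  # swing leg: zero
  expect_equal(knee_overextension_stimulation(0.02, -1, 0.12, 2, 0.3,
                                              stance = FALSE), 0)
})

test_that("stimulation components combine with rectification and clamping", {
  expect_equal(combine_stimulations(0.2), 0.2)
  expect_equal(combine_stimulations(0.5, 0.4, 0.3, 0), 1)
  expect_equal(combine_stimulations(0, 0, 0, 0), 0.001)
  # the rectification applies to the summed components
  expect_equal(combine_stimulations(-0.5, 0.2), 0.001)
  # swing-phase muscle: only the stretch reflex contributes
  expect_equal(combine_stimulations(0.37, 0, 0, 0), 0.37)
})

test_that("simulated stimulations stay within [floor, 1] and delays are honored", {
  p <- test_params
  sim <- run_simulation(p, test_model, duration = 1.5, log_muscles = TRUE)
  expect_gte(sim$stim_range[1], p$spinal$stim_floor)
  expect_lte(sim$stim_range[2], 1)
  scols <- grep("^S\\.", names(sim$muscles), value = TRUE)
  for (cc in scols) {
    expect_true(all(sim$muscles[[cc]] >= p$spinal$stim_floor - 1e-12))
    expect_true(all(sim$muscles[[cc]] <= 1 + 1e-12))
  }
})
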