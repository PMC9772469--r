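test_that("the unconstrained cost penalizes falls by distance walked", {
  met <- function(d_steady = NA, x_fall = NA) {
    tibble::tibble(step_length = 0.7, cadence = 110, speed = 1.28,
                   d_steady = d_steady, x_fall = x_fall, n_steps = 20,
                   valid = TRUE)
  }
  expect_equal(cost_unconstrained(met(x_fall = 3), fell = TRUE), 997)
  expect_equal(cost_unconstrained(met(d_steady = 0.4), fell = FALSE), 500.4)
  # every surviving gait outranks every falling one
  worst_survivor <- cost_unconstrained(met(d_steady = 50), FALSE)
  best_faller <- cost_unconstrained(met(x_fall = 400), TRUE)
  expect_lt(worst_survivor, best_faller)
})

test_that("the targeted cost applies its four stages in order", {
  cfg <- cost_config(cadence_target = 110, step_length_target = 0.7)
  expect_equal(cfg$v_tar, 110 * 0.7 / 60)
  met <- function(speed, cadence, d_steady = 0.1, x_fall = NA) {
    tibble::tibble(step_length = 0.7, cadence = cadence, speed = speed,
                   d_steady = d_steady, x_fall = x_fall, n_steps = 20,
                   valid = TRUE)
  }
  # stage 1: fell at 5 m
  expect_equal(cost_targeted(met(1, 110, x_fall = 5), TRUE, cfg), 995)
  # stage 2: speed error 0.5
  expect_equal(cost_targeted(met(cfg$v_tar + 0.5, 110), FALSE, cfg), 500.5)
  # stage 3: speed within tolerance, cadence error 5
  expect_equal(cost_targeted(met(cfg$v_tar + 0.01, 115), FALSE, cfg), 255)
  # stage 4: both within tolerance
  expect_equal(cost_targeted(met(cfg$v_tar + 0.01, 111, d_steady = 0.2),
                             FALSE, cfg), 125.2)
  # stages are ordered and non-interleaving for realistic magnitudes
  J <- c(cost_targeted(met(1, 110, x_fall = 5), TRUE, cfg),
         cost_targeted(met(cfg$v_tar + 0.5, 110), FALSE, cfg),
         cost_targeted(met(cfg$v_tar, 120), FALSE, cfg),
         cost_targeted(met(cfg$v_tar, 110), FALSE, cfg))
  expect_true(all(diff(J) < 0))
  expect_equal(cost_stage(J), 1:4)
})

test_that("reaching the final stage implies both tolerances are met", {
  cfg <- cost_config(110, 0.7)
  set.seed(4)
  for (i in 1:200) {
    sp <- cfg$v_tar + runif(1, -0.2, 0.2)
    cad <- 110 + runif(1, -10, 10)
    m <- tibble::tibble(step_length = 0.7, cadence = cad, speed = sp,
                        d_steady = runif(1, 0, 2), x_fall = NA,
                        n_steps = 20, valid = TRUE)
    J <- cost_targeted(m, FALSE, cfg)
    if (cost_stage(J) == 4) {
      expect_lte(abs(sp - cfg$v_tar), cfg$delta_v)
      expect_lte(abs(cad - cfg$cad_tar), cfg$delta_cad)
    }
  }
})

test_that("CMA-ES solves the sphere function to high precision", {
  res <- cma_es(function(x) sum(x^2), x0 = rep(0.5, 10), lower = -1,
                upper = 1, budget = 5000, seed = 1)
  expect_lt(res$value, 1e-8)
  expect_lte(res$evals, 5000)
  # best-so-far trace is non-increasing
  expect_true(all(diff(res$trace$best) <= 0))
})

test_that("CMA-ES is reproducible per seed and respects the box", {
  rosen <- function(x) sum(100 * (x[-1] - x[-5]^2)^2 + (1 - x[-5])^2)
  r1 <- cma_es(rosen, rep(0, 5), -2, 2, budget = 600, seed = 7)
  r2 <- cma_es(rosen, rep(0, 5), -2, 2, budget = 600, seed = 7)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace$best, r2$trace$best)
  r3 <- cma_es(rosen, rep(0, 5), -2, 2, budget = 600, seed = 8)
  expect_false(identical(r1$par, r3$par))
  expect_true(all(r1$par >= -2 & r1$par <= 2))
})

test_that("tidy and glance summarize optimizer results", {
  res <- cma_es(function(x) sum(x^2), rep(0.3, 4), -1, 1,
                budget = 200, seed = 2)
  td <- tidy(res)
  expect_true(all(c("generation", "best", "sigma") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$evals, res$evals)
})

test_that("the full parameter vector packs and unpacks consistently", {
  p <- test_params
  x <- gaitplanr:::pack_params(p, "all")
  expect_length(x, 44)   # 8 control + v_init + 8 balance + 27 spinal
  b <- parameter_bounds("all")
  expect_identical(names(x), b$name)
  x2 <- x; x2["K_l"] <- 5; x2["a_x"] <- 1.23
  p2 <- gaitplanr:::unpack_params(x2, p, "all")
  expect_equal(p2$spinal$K_l, 5)
  expect_equal(p2$control$a_x, 1.23)
  expect_equal(gaitplanr:::pack_params(p2, "all"), x2)
  # control subset: 9 values
  xc <- gaitplanr:::pack_params(p, "control")
  expect_length(xc, 9)
})

test_that("a tiny optimization run improves the walking cost", {
  res <- optimize_gait(test_params, "all", model = test_model, budget = 24,
                       seed = 3, duration = 4, lambda = 6)
  first_gen <- res$cma$trace$gen_best[1]
  expect_lte(res$value, first_gen)
  expect_s3_class(glance(res), "tbl_df")
})
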