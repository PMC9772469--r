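# Shared objects: load the default model and parameters once per test run.
test_model <- load_model()
test_params <- default_params()

# a reachable random configuration away from joint limits
random_config <- function() {
  q <- numeric(14)
  q[1:2] <- runif(2, -0.5, 0.5)
  q[3] <- runif(1, 0.9, 1.3)
  q[4:6] <- runif(3, -0.4, 0.4)
  lims <- test_model$cfg$joints$limits
  ord <- c("hipab", "hipfl", "knee", "ankle")
  for (leg in 0:1) {
    for (k in seq_along(ord)) {
      l <- lims[[ord[k]]]
      q[6 + 4 * leg + k] <- runif(1, l[1] + 0.1, l[2] - 0.1)
    }
  }
  q
}

random_velocity <- function() {
  qd <- runif(14, -1, 1)
  qd
}
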