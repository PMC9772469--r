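#' Covariance-matrix-adaptation evolution strategy
#'
#' Standard (mu/mu_w, lambda) CMA-ES minimizer with weighted recombination,
#' cumulative step-size adaptation and rank-one plus rank-mu covariance
#' updates, operating in a box: candidates are clamped to `[lower, upper]`
#' before evaluation. Deterministic for a fixed seed.
#'
#' @param fn Objective: takes a numeric vector, returns a scalar cost.
#' @param x0 Start point.
#' @param lower,upper Box bounds (recycled to `length(x0)`).
#' @param sigma0 Initial step size as a fraction of the bound range
#'   (default 0.1, i.e. 10% of each parameter's range).
#' @param budget Maximum number of function evaluations.
#' @param lambda Population size; default `4 + floor(3 log n)`.
#' @param seed Random seed (an integer).
#' @param callback Optional `function(gen, best_x, best_f)` called once per
#'   generation (e.g. for checkpointing).
#' @return A `cma_result`: `par` (best-ever point), `value` (its cost),
#'   `trace` (per-generation tibble), `evals`, `lambda`, `seed`.
#' @examples
#' res <- cma_es(function(x) sum(x^2), rep(0.5, 5), -1, 1,
#'               budget = 2000, seed = 1)
#' res$value < 1e-8
#' @export
cma_es <- function(fn, x0, lower, upper, sigma0 = 0.1, budget = 2000,
                   lambda = NULL, seed = 1, callback = NULL) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  range <- upper - lower
  stopifnot(all(range > 0), all(x0 >= lower - 1e-12), all(x0 <= upper + 1e-12))
  set.seed(as.integer(seed))
  # work in normalized coordinates [0, 1]^n
  z0 <- (x0 - lower) / range
  denorm <- function(z) lower + pmin(pmax(z, 0), 1) * range

  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- z0
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n); invsqrtC <- diag(n)
  eigen_stale <- 0

  best_f <- Inf; best_x <- denorm(m)
  evals <- 0L; gen <- 0L
  trace <- list()

  while (evals < budget) {
    gen <- gen + 1L
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- t(chol(C)) %*% Z            # C^{1/2} z
    X <- m + sigma * Y
    f <- numeric(lambda)
    for (k in seq_len(lambda)) {
      f[k] <- fn(denorm(X[, k]))
      evals <- evals + 1L
    }
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- denorm(X[, ord[1]])
    }
    m_old <- m
    m <- drop(X[, ord[seq_len(mu)], drop = FALSE] %*% w)
    yw <- (m - m_old) / sigma
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    artmp <- (X[, ord[seq_len(mu)], drop = FALSE] - m_old) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1)
    eigen_stale <- eigen_stale + 1
    if (eigen_stale >= max(1, floor(1 / (10 * n * (c1 + cmu))))) {
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      ev <- pmax(eg$values, 1e-14)
      invsqrtC <- eg$vectors %*% (t(eg$vectors) / sqrt(ev))
      C <- eg$vectors %*% (t(eg$vectors) * ev)
      eigen_stale <- 0
    }
    trace[[gen]] <- tibble::tibble(
      generation = gen, evals = evals, best = best_f,
      gen_best = f[ord[1]], gen_median = stats::median(f), sigma = sigma)
    if (!is.null(callback)) callback(gen, best_x, best_f)
  }
  structure(list(par = best_x, value = best_f,
                 trace = dplyr::bind_rows(trace),
                 evals = evals, lambda = lambda, seed = seed),
            class = "cma_result")
}

#' @export
print.cma_result <- function(x, ...) {
  cat(sprintf("<cma_result> best %.6g after %d evaluations (lambda %d)\n",
              x$value, x$evals, x$lambda))
  invisible(x)
}

#' @export
tidy.cma_result <- function(x, ...) x$trace

#' @export
glance.cma_result <- function(x, ...) {
  tibble::tibble(best = x$value, evals = x$evals,
                 generations = nrow(x$trace), lambda = x$lambda,
                 seed = x$seed)
}
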