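# Independent oracles, implemented directly from the model configuration
# file without touching the package's dynamics code.

rot_axis <- function(a, th) {
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# forward kinematics of the walker re-derived from the YAML configuration:
# returns per-body world rotation and CoM position, plus mass and local
# inertia, for the 7 massive bodies
oracle_fk <- function(cfg, q) {
  hip_y <- cfg$trunk$hip_offset_y
  L_th <- cfg$thigh$length
  L_sh <- cfg$shank$length
  bodies <- list()
  # trunk chain: translations then yaw(z), pitch(y), roll(x)
  R <- rot_axis(c(0, 0, 1), q[4]) %*% rot_axis(c(0, 1, 0), q[5]) %*%
    rot_axis(c(1, 0, 0), q[6])
  p <- c(q[1], q[2], q[3])
  bodies$trunk <- list(R = R, com = p + R %*% unlist(cfg$trunk$com),
                       m = cfg$trunk$mass, I = diag(unlist(cfg$trunk$inertia)))
  for (leg in 0:1) {
    sy <- if (leg == 0) 1 else -1
    p_hip <- p + R %*% c(0, sy * hip_y, 0)
    R_ab <- R %*% rot_axis(c(sy, 0, 0), q[7 + 4 * leg])
    R_th <- R_ab %*% rot_axis(c(0, -1, 0), q[8 + 4 * leg])
    p_knee <- p_hip + R_th %*% c(0, 0, -L_th)
    R_sh <- R_th %*% rot_axis(c(0, 1, 0), q[9 + 4 * leg])
    p_ank <- p_knee + R_sh %*% c(0, 0, -L_sh)
    R_ft <- R_sh %*% rot_axis(c(0, -1, 0), q[10 + 4 * leg])
    fc <- unlist(cfg$foot$com); fc[2] <- fc[2] * sy
    side <- if (leg == 0) "l" else "r"
    bodies[[paste0("thigh_", side)]] <- list(
      R = R_th, com = p_hip + R_th %*% unlist(cfg$thigh$com),
      m = cfg$thigh$mass, I = diag(unlist(cfg$thigh$inertia)))
    bodies[[paste0("shank_", side)]] <- list(
      R = R_sh, com = p_knee + R_sh %*% unlist(cfg$shank$com),
      m = cfg$shank$mass, I = diag(unlist(cfg$shank$inertia)))
    bodies[[paste0("foot_", side)]] <- list(
      R = R_ft, com = p_ank + R_ft %*% fc,
      m = cfg$foot$mass, I = diag(unlist(cfg$foot$inertia)))
  }
  bodies
}

# kinetic energy at (q, qdot) by numerical differentiation of the oracle
# forward kinematics along q(t) = q + qdot t
oracle_ke <- function(cfg, q, qd, h = 1e-5) {
  b0 <- oracle_fk(cfg, q - h * qd)
  b1 <- oracle_fk(cfg, q + h * qd)
  ke <- 0
  for (nm in names(b0)) {
    v <- (b1[[nm]]$com - b0[[nm]]$com) / (2 * h)
    Rdot <- (b1[[nm]]$R - b0[[nm]]$R) / (2 * h)
    Rm <- oracle_fk(cfg, q)[[nm]]$R
    W <- Rdot %*% t(Rm)
    w <- c(W[3, 2], W[1, 3], W[2, 1])
    Iw <- Rm %*% b0[[nm]]$I %*% t(Rm)
    ke <- ke + 0.5 * b0[[nm]]$m * sum(v^2) + 0.5 * sum(w * (Iw %*% w))
  }
  ke
}

# mass matrix from the bilinearity of the kinetic energy
oracle_mass_matrix <- function(cfg, q) {
  n <- 14
  M <- matrix(0, n, n)
  kes <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    oracle_ke(cfg, q, e)
  }, numeric(1))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        M[i, i] <- 2 * kes[i]
      } else {
        e <- numeric(n); e[i] <- 1; e[j] <- 1
        M[i, j] <- M[j, i] <- oracle_ke(cfg, q, e) - kes[i] - kes[j]
      }
    }
  }
  M
}

# generalized gravity forces from the potential-energy gradient
oracle_gravity <- function(cfg, q, h = 1e-6) {
  V <- function(qq) {
    b <- oracle_fk(cfg, qq)
    sum(vapply(b, function(x) x$m * x$com[3], numeric(1))) * cfg$gravity
  }
  vapply(seq_len(14), function(i) {
    e <- numeric(14); e[i] <- h
    -(V(q + e) - V(q - e)) / (2 * h)
  }, numeric(1))
}

# brute-force oracle for min sum F^2 s.t. R F = tau, F >= 0:
# enumerate all active sets (muscles pinned at zero), solve the
# equality-constrained problem on the rest, keep the best feasible point
oracle_qp <- function(R, tau, tol = 1e-9) {
  k <- ncol(R)
  best <- NULL; best_val <- Inf
  for (mask in 0:(2^k - 1)) {
    free <- which(bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1) == 0)
    Fv <- numeric(k)
    if (length(free)) {
      Rf <- R[, free, drop = FALSE]
      G <- Rf %*% t(Rf)
      if (abs(det(G)) < 1e-12) next
      Ff <- t(Rf) %*% solve(G, tau)
      Fv[free] <- Ff
    }
    if (any(Fv < -tol)) next
    if (max(abs(R %*% Fv - tau)) > 1e-7) next
    val <- sum(Fv^2)
    if (val < best_val - 1e-12) { best_val <- val; best <- Fv }
  }
  best
}

# explicit minimum-norm least-squares oracle via SVD (independent of the
# implementation's pseudoinverse path)
oracle_pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}
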