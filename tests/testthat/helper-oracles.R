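# Independent numerical oracles used across the suite.

# central-difference Jacobian of a vector field, independent of the
# analytic assembly in the package
fd_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, length(f(x)), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

# central-difference derivative of a scalar function of y
fd_deriv <- function(f, y, h = 1e-5) (f(y + h) - f(y - h)) / (2 * h)

# bisection for the smallest speed keeping the Fisher-type slice (alpha = 0)
# non-negative; independent route used by the acceptance criterion
fisher_minimal_speed_bisect <- function(kappa = 1, bracket = c(1, 3),
                                        tol = 0.01) {
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r <- shoot(0, mid, kappa, on_unresolved = "state")
    if (r$outcome == "EXITS_N_ZERO") lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# turn a dense shot's n-component into a smooth function of y with the
# correct asymptotic tails, for quadrature oracles (cubic interpolation so
# the quadrature is not limited by piecewise-linear error)
n_path_from_shot <- function(shot_res) {
  traj <- shot_res$trajectory
  sp <- stats::splinefun(traj$y, traj$n, method = "fmm")
  lo <- min(traj$y); hi <- max(traj$y)
  function(y) {
    out <- numeric(length(y))
    inside <- y >= lo & y <= hi
    out[y < lo] <- 1
    out[y > hi] <- 0
    out[inside] <- pmin(1, pmax(0, sp(y[inside])))
    out
  }
}
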