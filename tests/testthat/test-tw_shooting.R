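test_that("desingularized vector field matches direct substitution", {
  expect_equal(rhs_desingularized(c(1, 0, 0), 2, 1), c(0, 0, 0))
  for (mb in c(0, 0.3, 0.8))
    expect_equal(rhs_desingularized(c(0, 0, mb), 1.3, 2), c(0, 0, 0))
  expect_equal(rhs_desingularized(c(0.5, -0.1, 0.5), c = 1, kappa = 2),
               c(-0.1, -0.025, 0.25), tolerance = 1e-15)
  expect_error(rhs_desingularized(c(0.5, 0, 0.5), 0, 1), "c = 0")
})

test_that("launch point follows the unstable-manifold expansion", {
  lp <- launch_point(0, 2, 1)
  expect_equal(unname(lp$state["m"]), 0)
  # direct evaluation: c = 2, kappa = 1, alpha = 1, y0 = -45 has
  # lambda3 = 1/2, so m(y0) = exp(-22.5)
  lp <- launch_point(1, 2, 1, y0 = -45)
  expect_equal(unname(lp$state["m"]), exp(-22.5), tolerance = 1e-12)
  # deeper launches approach the equilibrium (1, 0, 0)
  l2 <- spectrum_invaded(2, 1)$eigenvalues[["lambda2"]]
  d1 <- launch_point(1, 2, 1, y0 = -45)$state - c(1, 0, 0)
  d2 <- launch_point(1, 2, 1, y0 = -60)$state - c(1, 0, 0)
  expect_lt(max(abs(d2)), max(abs(d1)))
  # too-shallow launches are rejected (truncated terms not negligible)
  expect_error(launch_point(1, 2, 1, y0 = -2), "too shallow")
})

test_that("shot outcomes cover the classification: Fisher front, exit, degenerate", {
  r <- shoot(0, 2, 1)
  expect_equal(r$outcome, "CONVERGES_PARTIAL")
  expect_equal(r$m_inf, 0)
  r <- shoot(1e-6, 1, 1)
  expect_equal(r$outcome, "EXITS_N_ZERO")
  expect_true(is.finite(r$T))
  expect_lt(r$p_at_T, 0)
  r <- shoot(1000, 1, 1)
  expect_equal(r$outcome, "CONVERGES_DEGENERATE")
  expect_true(r$not_a_TWS)
  expect_gt(r$n_inf, 0)
  expect_lt(r$n_inf, 1)
})

test_that("resolved shots obey the limit dichotomy (partial m excludes positive n)", {
  probes <- expand.grid(alpha = c(0.05, 0.3, 1, 3, 8), c = c(1, 2))
  for (i in seq_len(nrow(probes))) {
    r <- shoot(probes$alpha[i], probes$c[i], 1, on_unresolved = "state")
    if (r$outcome == "CONVERGES_PARTIAL") {
      expect_equal(r$n_inf, 0)
      expect_equal(r$p_inf, 0)
      expect_lt(r$m_inf, 1)
    }
    if (r$outcome == "CONVERGES_DEGENERATE" && r$resolved == "event") {
      expect_gt(r$n_inf, 1e-6)
      expect_equal(r$m_inf, 1, tolerance = 1e-8)
    }
  }
})

test_that("reached far-field density is strictly increasing in alpha", {
  set.seed(3)
  a <- sort(runif(40, 0.01, 1.2))  # stays below the degenerate regime at c = 2
  m_inf <- vapply(a, function(al) shoot(al, 2, 1, on_unresolved = "state")$m_inf,
                  numeric(1))
  expect_true(all(diff(m_inf) > 0))  # 20+ ordered probe pairs
})

test_that("first-zero location is non-decreasing in alpha at fixed speed", {
  a <- c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1)
  T <- vapply(a, function(al) shoot(al, 1, 1, on_unresolved = "state")$T,
              numeric(1))
  T <- T[is.finite(T)]
  expect_gte(length(T), 3)
  expect_true(all(diff(T) >= 0))
})

test_that("trajectories are insensitive to the launch depth", {
  l2 <- spectrum_invaded(2, 1)$eigenvalues[["lambda2"]]
  y0 <- log(1e-8) / l2
  m1 <- shoot(0.5, 2, 1, y0 = y0)$m_inf
  m2 <- shoot(0.5, 2, 1, y0 = y0 - 10)$m_inf
  expect_lt(abs(m1 - m2), 1e-6)
})

test_that("closed-form ECM component solves the m-equation and hits its limits", {
  # n identically 0: m constant at m_bar
  m <- closed_form_m(function(y) 0 * y, 0.5, 1, 1)
  expect_equal(m(c(-5, 0, 5)), rep(0.5, 3), tolerance = 1e-12)
  # logistic n: residual of the m-equation below 1e-8 across y in [-20, 20]
  n_fun <- function(y) 1 / (1 + exp(y))
  m <- closed_form_m(n_fun, 0.5, 1, 1)
  y <- seq(-20, 20, by = 2.5)
  resid <- fd_deriv(m, y) - (1 / 1) * m(y) * (1 - m(y)) * n_fun(y)
  expect_lt(max(abs(resid)), 1e-8)
  # divergent left-tail integral drives m to 0
  expect_lt(m(-30), 1e-10)
  expect_error(closed_form_m(n_fun, 1.2, 1, 1), "inside \\(0, 1\\)")
})

test_that("closed form reproduces the m-component of integrated partial orbits", {
  for (alpha in c(0.3, 0.8)) {
    r <- shoot(alpha, 2, 1, dense = TRUE)
    expect_equal(r$outcome, "CONVERGES_PARTIAL")
    m_oracle <- closed_form_m(n_path_from_shot(r), r$m_inf, 2, 1)
    traj <- r$trajectory
    idx <- seq(10, nrow(traj) - 1, length.out = 25)
    err <- abs(m_oracle(traj$y[idx]) - traj$m[idx])
    expect_lt(max(err), 1e-6)
  }
})

test_that("alpha0 vanishes for supercritical speeds and is positive below c = 2", {
  a0 <- find_alpha0(2.5, 1, tol_alpha = 1e-6)
  expect_equal(a0$alpha0, 0)
  expect_lte(diff(a0$bracket), 1e-6)
  a0 <- find_alpha0(1, 1, tol_alpha = 1e-4)
  expect_gt(a0$alpha0, 0)
})

test_that("alpha1 orbit connects to (0,0,1) and satisfies the algebraic decay law", {
  res <- find_alpha1(1, 1)
  expect_gt(res$alpha1, 0)
  crit <- res$result
  expect_true(crit$outcome %in% c("CONVERGES_P2", "CONVERGES_PARTIAL"))
  expect_gt(crit$m_inf, 0.99)
  ratios <- decay_law_check(crit)
  expect_lt(abs(ratios[["ratio_m"]] - 1), 0.1)
  expect_lt(abs(ratios[["ratio_n"]] - 1), 0.1)
})

test_that("target search brackets the unique alpha and reports infeasibility", {
  # m_bar = 0 short-circuits to the Fisher slice
  f <- find_alpha_for_target(2, 1, 0)
  expect_equal(f$alpha, 0)
  expect_true(f$feasible)
  # unique admissible alpha strictly inside (0, alpha1)
  f <- find_alpha_for_target(2, 1, 0.5)
  expect_true(f$feasible)
  expect_equal(f$m_inf, 0.5, tolerance = 1e-6)
  expect_gt(f$alpha, 0)
  expect_lt(f$alpha, find_alpha1(2, 1)$alpha1)
  # below the spiral bound no admissible monotone connection exists
  f <- find_alpha_for_target(0.5, 1, 0.9)  # 2 sqrt(0.1) = 0.632 > 0.5
  expect_false(f$feasible)
  expect_equal(f$status, "INFEASIBLE")
})

test_that("no admissible monotone connection exists below the spiral bound", {
  # Sturm-type property: c < 2 sqrt(1 - m_bar) forces every shot to exit or
  # overshoot; none converges admissibly to the target
  cc <- 0.5; m_bar <- 0.9
  alphas <- exp(seq(log(1e-3), log(50), length.out = 50))
  for (al in alphas) {
    r <- shoot(al, cc, 1, on_unresolved = "state")
    admissible_hit <- r$outcome == "CONVERGES_PARTIAL" &&
      abs(r$m_inf - m_bar) < 1e-3
    expect_false(admissible_hit)
  }
})

test_that("physical profile reconstruction inverts the desingularization", {
  # Fisher slice: m = 0, so xi is y up to translation
  r <- shoot(0, 2, 1, dense = TRUE)
  prof <- reconstruct_physical_profile(r)
  dy <- diff(r$trajectory$y)
  expect_equal(diff(prof$xi), dy, tolerance = 1e-9)
  # generic admissible orbit: xi strictly increasing, N down, M up
  f <- find_alpha_for_target(2, 1, 0.5, dense = TRUE)
  prof <- reconstruct_physical_profile(f$result)
  expect_true(all(diff(prof$xi) > 0))
  expect_true(all(diff(prof$N) < 1e-12))
  expect_true(all(diff(prof$M) > -1e-12))
  expect_equal(stats::approx(prof$xi, prof$N, xout = 0)$y, 0.5,
               tolerance = 1e-6)
  # non-waves are rejected
  bad <- shoot(1000, 1, 1, dense = TRUE)
  expect_error(reconstruct_physical_profile(bad), "not a travelling wave")
})
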