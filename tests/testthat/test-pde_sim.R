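test_that("initial condition evaluates the bump profile exactly", {
  ic <- ic_params(L = 200, sigma = 2, omega = 1, M_bar = 0.4)
  st <- build_initial_condition(ic, 2001)
  # x = sigma: third branch
  i <- which(st$x == 2)
  expect_equal(st$N[i], 0)
  expect_equal(st$M[i], 0.4)
  # x = sigma - omega: continuous with the plateau
  i <- which(st$x == 1)
  expect_equal(st$N[i], 1)
  # x = sigma - omega/2: direct bump evaluation exp(1 - 1/(1 - 0.25))
  i <- which(st$x == 1.5)
  expect_equal(st$N[i], exp(-1 / 3), tolerance = 1e-12)
  expect_equal(st$M[i], 0.4 * (1 - exp(-1 / 3)), tolerance = 1e-12)
  expect_error(ic_params(200, 2, 3, 0.4), "omega < sigma")
  expect_error(ic_params(200, 2, 1, 1.5), "M_bar")
})

test_that("semidiscrete RHS vanishes at steady states and telescopes conservatively", {
  ic <- ic_params(M_bar = 0.5)
  st <- build_initial_condition(ic, 401)
  # invaded steady state
  st1 <- st; st1$N[] <- 1; st1$M[] <- 0
  d <- semidiscrete_rhs(st1, kappa = 1)
  expect_equal(max(abs(d$dN)), 0)
  expect_equal(max(abs(d$dM)), 0)
  # tumour-free steady state
  st2 <- st; st2$N[] <- 0; st2$M[] <- 0.7
  d <- semidiscrete_rhs(st2, kappa = 1)
  expect_equal(max(abs(d$dN)), 0)
  expect_equal(max(abs(d$dM)), 0)
  # conservative telescoping: diffusion part sums to zero for random states
  set.seed(7)
  dx <- st$x[2] - st$x[1]
  for (i in 1:20) {
    st$N <- runif(length(st$x)); st$M <- runif(length(st$x))
    d <- semidiscrete_rhs(st, kappa = 2)
    diffusion <- d$dN - st$N * (1 - st$N)
    expect_lt(abs(sum(diffusion) * dx), 1e-12)
  }
  st$x <- st$x^1.01
  expect_error(semidiscrete_rhs(st, 1), "uniform")
})

test_that("M decays monotonically in time and N respects the comparison bound", {
  for (dx in c(0.2, 0.1, 0.05)) {
    sol <- solve_invasion(ic_params(L = 50, M_bar = 0.5), kappa = 1,
                          t_end = 20, dx = dx,
                          output_times = seq(0, 20, by = 2))
    expect_true(all(diff(sol$M) <= 1e-12))   # columnwise differences in time
    expect_lt(max(sol$N), 1 + 1e-6)
    expect_gt(min(sol$N), -1e-10)
  }
})

test_that("front tracking interpolates level crossings exactly and flags absences", {
  # synthetic solution: step at 37.5 smoothed linearly over one cell
  x <- seq(0, 100, by = 0.5)
  N <- ifelse(x < 37.25, 1, ifelse(x > 37.75, 0, (37.75 - x) / 0.5))
  sol <- structure(list(x = x, times = c(0, 1),
                        N = rbind(N, N), M = rbind(0 * N, 0 * N),
                        kappa = 1, dx = 0.5,
                        ic = ic_params(L = 100, M_bar = 0)),
                   class = "ecm_pde_solution")
  tr <- track_front(sol)
  expect_equal(tr$X, c(37.5, 37.5), tolerance = 1e-12)
  # profile below the level everywhere: flagged, no position
  sol$N <- rbind(N * 0.3, N * 0.3)
  expect_true(all(is.na(track_front(sol)$X)))
  # multiple crossings: error
  sol$N <- rbind(N, N)
  sol$N[1, x > 60 & x < 62] <- 0.8
  expect_error(track_front(sol), "multiple")
})

test_that("speed estimation recovers an exact line and enforces the point minimum", {
  tr <- structure(data.frame(t = 0:100, X = 3 + 1.5 * (0:100)),
                  class = c("ecm_front_trace", "data.frame"))
  est <- estimate_speed(tr, window = c(50, 100))
  expect_equal(est$c_hat, 1.5, tolerance = 1e-12)
  expect_equal(est$rms_residual, 0, tolerance = 1e-10)
  short <- structure(data.frame(t = seq(0, 100, by = 20), X = seq(0, 100, by = 20)),
                     class = c("ecm_front_trace", "data.frame"))
  expect_error(estimate_speed(short, window = c(50, 100)), "at least 10")
})

test_that("self-convergence of the Fisher-type front speed under grid refinement", {
  ic <- ic_params(M_bar = 0)
  tab <- convergence_check(ic, kappa = 1, dx_list = c(0.2, 0.1))
  expect_lt(tab$rel_diff[2], 0.01)
  expect_error(convergence_check(ic, 1, dx_list = 0.1), "two entries")
  expect_error(convergence_check(ic, 1, dx_list = c(0.1, 0.2)), "decreasing")
})

test_that("compact-support initial-condition variants select the same speed", {
  base <- ic_params(M_bar = 0.25)
  vars <- make_ic_variants(base, 3, seed = 11, n_nodes = 1001)
  speeds <- vapply(vars, function(v) {
    sol <- solve_invasion(base, kappa = 1, t_end = 60, dx = 0.2,
                          state0 = v$payload)
    estimate_speed(track_front(sol), window = c(30, 60))$c_hat
  }, numeric(1))
  expect_lt(diff(range(speeds)) / mean(speeds), 0.02)
})
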