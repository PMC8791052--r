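test_that("initial-condition variants are compactly supported and bitwise reproducible", {
  base <- ic_params(M_bar = 0.3)
  v1 <- make_ic_variants(base, 4, seed = 5, n_nodes = 801)
  v2 <- make_ic_variants(base, 4, seed = 5, n_nodes = 801)
  expect_identical(v1, v2)
  # variant 0 is exactly the reference profile
  ref <- build_initial_condition(base, 801)
  expect_identical(v1[[1]]$payload$N, ref$N)
  expect_identical(v1[[1]]$payload$M, ref$M)
  for (v in v1) {
    N <- v$payload$N; M <- v$payload$M
    expect_equal(N[length(N)], 0)            # compact support
    expect_true(all(N >= 0 & N <= 1))
    ramp <- N > 0 & N < 1
    expect_equal(M[ramp], 0.3 * (1 - N[ramp]), tolerance = 1e-12)
    expect_true(all(M[N == 0] == 0.3))
  }
  # a different seed perturbs the non-reference variants
  v3 <- make_ic_variants(base, 4, seed = 6, n_nodes = 801)
  expect_identical(v1[[1]]$payload$N, v3[[1]]$payload$N)
  expect_false(identical(v1[[2]]$payload$N, v3[[2]]$payload$N))
})

test_that("manufactured orbit satisfies the m-equation by construction", {
  fx <- manufactured_trajectory(0.5, 1, 1)
  n <- fx$payload$n; m <- fx$payload$m
  y <- seq(-20, 20, by = 4)
  # strictly increasing with the right limits
  expect_true(all(diff(m(y)) > 0))
  expect_lt(m(-20), 1e-6)
  expect_lt(abs(m(20) - 0.5), 1e-6)   # tail integral below exp(-20)
  resid <- fd_deriv(m, y) - m(y) * (1 - m(y)) * n(y)
  expect_lt(max(abs(resid)), 1e-8)
  expect_error(manufactured_trajectory(0, 1, 1), "inside \\(0, 1\\)")
})

test_that("report tables regenerate identically across output directories", {
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  args <- list(kappa = 1, M_bar_front = 0.25, kappa_front = 1,
               M_bar_sweep = c(0, 0.5), M_bar_profile = 0.5,
               dx = 0.4, t_end = 60)
  do.call(report_tables, c(list(out_dir = d1), args))
  do.call(report_tables, c(list(out_dir = d2), args))
  files <- c("fig2_front_positions.csv", "fig3b_speed_vs_mbar.csv",
             "fig4_profile_comparison.csv", "summary.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  tab <- utils::read.csv(file.path(d1, "fig3b_speed_vs_mbar.csv"))
  expect_equal(nrow(tab), 2)  # one row per M_bar value
})
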