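test_that("nondimensionalization reduces to kappa = (K/rho) k and rejects bad input", {
  expect_equal(nondimensionalize(dimensional_params(1, 1, 1, 1, 1))$kappa, 1)
  expect_equal(nondimensionalize(dimensional_params(1, 0.5, 2, 0.25, 1))$kappa, 1)
  expect_error(dimensional_params(1, 1, 1, 0, 1), "'k'")
  expect_error(dimensional_params(-1, 1, 1, 1, 1), "'D_N'")
  expect_error(model_params(0), "kappa")
})

test_that("steady states comprise the three isolated states and the tumour-free family", {
  ss <- steady_states()
  inv <- ss$states[ss$states$label == "invaded", ]
  expect_equal(c(inv$N, inv$M), c(1, 0))
  tf <- ss$states[ss$states$label == "tumour_free_max", ]
  expect_equal(c(tf$N, tf$M), c(0, 1))
  fam <- steady_states(M_bar = 0.3)$sample
  expect_equal(c(fam$N, fam$M), c(0, 0.3))
  expect_error(ss$family(1), "\\[0, 1\\)")
})

test_that("invaded-state spectrum matches a numeric eigensolver on the finite-difference Jacobian", {
  set.seed(42)
  for (i in 1:100) {
    cc <- runif(1, 0.2, 4)
    kap <- runif(1, 0.05, 20)
    sp <- spectrum_invaded(cc, kap)
    f <- function(s) rhs_desingularized(s, cc, kap)
    J <- fd_jacobian(f, c(1, 0, 0))
    ev_num <- sort(Re(eigen(J, only.values = TRUE)$values))
    expect_lt(max(abs(ev_num - sort(sp$eigenvalues))), 1e-7) # fd-limited
    # analytic Jacobian agrees with the generic solver to full precision
    Ja <- jacobian_desingularized(c(1, 0, 0), cc, kap)
    ev_exact <- sort(Re(eigen(Ja, only.values = TRUE)$values))
    expect_lt(max(abs(ev_exact - sort(sp$eigenvalues))), 1e-10)
    # eigen-relation residual for every returned pair
    for (j in 1:3) {
      v <- sp$eigenvectors[, j]
      expect_lt(max(abs(Ja %*% v - sp$eigenvalues[j] * v)), 1e-10)
    }
  }
})

test_that("invaded-state spectrum satisfies the Vieta identities and printed values", {
  sp <- spectrum_invaded(2, 1)
  expect_equal(unname(sp$eigenvalues), c((-2 - sqrt(8)) / 2, (-2 + sqrt(8)) / 2, 0.5),
               tolerance = 1e-12)
  for (cc in c(0.5, 1, 2, 3.7)) for (kap in c(0.2, 1, 5)) {
    ev <- spectrum_invaded(cc, kap)$eigenvalues
    expect_equal(unname(ev[1] * ev[2]), -1, tolerance = 1e-12)
    expect_equal(unname(ev[1] + ev[2]), -cc, tolerance = 1e-12)
    expect_equal(unname(ev[3]), kap / cc, tolerance = 1e-12)
  }
  expect_error(spectrum_invaded(-1, 1), "positive")
})

test_that("tumour-free spectrum flags the spiral transition at c = 2 sqrt(1 - m)", {
  sp <- spectrum_tumour_free(2, 0)
  expect_false(sp$complex_pair)
  expect_equal(unname(sp$eigenvalues), c(-1, -1, 0), tolerance = 1e-12)
  expect_true(spectrum_tumour_free(1, 0)$complex_pair)
  for (m in c(0, 0.3, 0.6, 0.9)) {
    ctrans <- 2 * sqrt(1 - m)
    expect_true(spectrum_tumour_free(ctrans * 0.99, m)$complex_pair)
    expect_false(spectrum_tumour_free(ctrans * 1.01, m)$complex_pair)
  }
  expect_error(spectrum_tumour_free(1, 1), "\\[0, 1\\)")
})

test_that("thresholds obey the kappa*/m* duality and the speed-bound structure", {
  th <- thresholds(1, 0.5)
  expect_equal(th$kappa_star, 1)
  expect_equal(th$m_star, 0.5)
  expect_equal(thresholds(1, 0.75)$c_lower, 1)
  expect_equal(thresholds(1, 0)$c_lower, 2)
  expect_equal(thresholds(1, 0)$kappa_star, Inf)
  for (m in seq(0.05, 0.95, by = 0.1)) {
    ks <- thresholds(1, m)$kappa_star
    expect_equal(thresholds(ks, m)$m_star, m, tolerance = 1e-12)
  }
  # c_lower strictly decreasing and equal to the spiral transition
  ms <- seq(0, 0.9, by = 0.1)
  cl <- vapply(ms, function(m) thresholds(1, m)$c_lower, numeric(1))
  expect_true(all(diff(cl) < 0))
  for (m in ms[ms > 0]) {
    expect_false(spectrum_tumour_free(thresholds(1, m)$c_lower + 1e-9, m)$complex_pair)
    expect_true(spectrum_tumour_free(thresholds(1, m)$c_lower - 1e-6, m)$complex_pair)
  }
  expect_error(thresholds(1, 1), "\\[0, 1\\)")
})
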