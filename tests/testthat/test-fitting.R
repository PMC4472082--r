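test_that("effective uncertainty combines error sources in quadrature", {
  expect_equal(effective_uncertainty(0.5), 0.5)
  expect_equal(effective_uncertainty(3, 4, 0, 0), 5)
  expect_equal(effective_uncertainty(0.5, 0.2, 0.3, 1), 0.6164, tolerance = 1e-4)
  expect_error(effective_uncertainty(0, 0, 0, 0), "infinite weight")
})

test_that("chi-squared matches its definition and counts 2n - 3 freedoms", {
  ds <- stress_dataset(P = c(1e4, 1e5, 1e6), d_W = c(15, 12, 9),
                       Delta = c(6, 5, 3.5), U_dW = 0.5, U_Delta = 0.3,
                       U_P_rel = 0)
  sim_exact <- data.frame(P = ds$P_Pa, d_W = ds$dW_A, Delta = ds$Delta_A,
                          U_sim_dW = 0, U_sim_Delta = 0)
  ch <- chi_squared(ds, sim_exact)
  expect_equal(ch$chi2, 0)
  expect_equal(ch$n_free, 3L)
  # one observable off by exactly one effective sigma
  sim1 <- sim_exact
  sim1$d_W[2] <- sim1$d_W[2] + 0.5
  expect_equal(chi_squared(ds, sim1)$chi2, 1)
  # 10 pressure points: Ntilde = 2*10 - 3 = 17
  ds10 <- stress_dataset(P = seq(1e4, 1e6, length.out = 10),
                         d_W = seq(15, 9, length.out = 10),
                         Delta = seq(6, 3, length.out = 10),
                         U_dW = 0.5, U_Delta = 0.3)
  sim10 <- data.frame(P = ds10$P_Pa, d_W = ds10$dW_A, Delta = ds10$Delta_A,
                      U_sim_dW = 0, U_sim_Delta = 0)
  ch10 <- chi_squared(ds10, sim10)
  expect_equal(ch10$n_free, 17L)
  expect_equal(ch10$chi2_red, ch10$chi2 / 17)
  # missing simulated pressures are reported by value
  expect_error(chi_squared(ds, sim_exact[-2, ]), "1e\\+05|100000")
})

test_that("pressure-grid derivative is exact for linear observables", {
  P <- c(0, 2e4, 1e5, 4e5, 1e6)
  f <- 17 - 3e-6 * P
  expect_equal(lamstack:::grid_derivative(P, f), rep(-3e-6, 5),
               tolerance = 1e-12)
})

test_that("chi-squared vanishes on noise-free self-generated data", {
  lam_true <- list(logA = 8.3, lam = 1.37, K_c = 44)
  tmpl <- ld_params()
  opts <- list(N = 6, M = 4, n_equil = 500, n_collect = 2000)
  iso <- suppressWarnings(lamstack:::simulate_isotherm(
    c(5e4, 3e5, 2e6), lam_true, tmpl, opts, seed = 400))
  ds <- stress_dataset(iso$table$P, iso$table$d_W, iso$table$Delta,
                       U_dW = 0.3, U_Delta = 0.2, U_P_rel = 1e-6)
  iso2 <- suppressWarnings(lamstack:::simulate_isotherm(
    c(5e4, 3e5, 2e6), lam_true, tmpl, opts, seed = 400))
  ch <- chi_squared(ds, iso2$table)
  expect_lt(ch$chi2_red, 0.1)  # identical seeds: residuals are exactly zero
})

test_that("fit accepts only improving steps and is row-order invariant", {
  lam_true <- list(logA = 8.3, lam = 1.37, K_c = 44)
  tmpl <- ld_params()
  opts <- list(N = 6, M = 4, n_equil = 500, n_collect = 2000)
  iso <- suppressWarnings(lamstack:::simulate_isotherm(
    c(5e4, 3e5, 2e6), lam_true, tmpl, opts, seed = 400))
  ds <- stress_dataset(iso$table$P, iso$table$d_W, iso$table$Delta,
                       U_dW = 0.4, U_Delta = 0.25)
  start <- list(logA = 8.15, lam = 1.5, K_c = 55)
  f1 <- suppressWarnings(fit_interaction_params(
    ds, start = start, template = tmpl, sim_opts = opts,
    max_iter = 3, seed = 500))
  # objective is monotone over the iteration trace (accepted steps only)
  chis <- f1$trace[, "chi2"]
  expect_true(all(diff(chis) <= 1e-9))
  # reordering the dataset rows changes nothing
  ds_rev <- ds[nrow(ds):1, ]
  class(ds_rev) <- class(ds)
  f2 <- suppressWarnings(fit_interaction_params(
    ds_rev, start = start, template = tmpl, sim_opts = opts,
    max_iter = 3, seed = 500))
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-10)
  expect_equal(f1$params, f2$params, tolerance = 1e-10)
  expect_s3_class(f1, "fit_result")
  expect_true(all(is.finite(f1$param_errors)))
})

test_that("fit input validation", {
  ds <- stress_dataset(P = c(1e4, 1e5), d_W = c(15, 12), Delta = c(6, 5),
                       U_dW = 0.5, U_Delta = 0.3)
  expect_error(fit_interaction_params(ds, template = ld_params()),
               "at least 3")
  expect_error(stress_dataset(P = 1e4, d_W = -2, Delta = 1, U_dW = 1,
                              U_Delta = 1), "positive")
})
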