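test_that("bare potential matches hand-evaluated reference values", {
  # pure hydration: Phi(0) = A * lambda
  p_hyd <- interaction_params(A = 10^8.3, lam = 1.37, H = 0, steric = FALSE)
  # 10^8.3 Pa * 1.37 A = 2.7338e8 Pa*A = 2.7338e-2 J/m^2 = 0.27338 zJ/A^2
  expect_equal(bare_potential(0, p_hyd), 0.273351, tolerance = 1e-5)
  # pure vdW at 20 A with H = 4.08 zJ: -H/(12 pi a^2)
  p_vdw <- interaction_params(A = 1e-30, lam = 1.37, H = 4.08, steric = FALSE)
  expect_equal(bare_potential(20, p_vdw), -2.7057e-4, tolerance = 1e-4)
  # decay to zero at large separations
  p_full <- interaction_params(A = 10^8.3, lam = 1.37, H = 4.08)
  expect_lt(abs(bare_potential(1e4, p_full)), 1e-8)
  # domain error
  expect_error(bare_potential(-1, p_full), "non-negative")
})

test_that("potential is continuous at the vdW cutoff and finite below it", {
  p <- interaction_params(A = 10^8.3, lam = 1.37, H = 4.08)
  eps <- 1e-9
  below <- bare_potential(p$a_cut - eps, p)
  above <- bare_potential(p$a_cut + eps, p)
  expect_equal(below, above, tolerance = 1e-6)
  expect_true(is.finite(bare_potential(0, p)))
  # clamped, not dropped: the vdW term contributes its cutoff value at a = 0
  p0 <- interaction_params(A = 10^8.3, lam = 1.37, H = 0)
  expect_equal(bare_potential(0, p) - bare_potential(0, p0),
               -4.08 / (12 * pi * 1^2), tolerance = 1e-12)
})

test_that("bare pressures match hand arithmetic and exponential/cubic laws", {
  p <- interaction_params(A = 10^8.3, lam = 1.37, H = 4.08)
  expect_equal(bare_pressure_hydration(0, p), 10^8.3)
  expect_equal(bare_pressure_hydration(14, p), 7277.0, tolerance = 1e-4)
  # ratio e between spacings one decay length apart
  d <- c(3, 7.7, 12)
  expect_equal(bare_pressure_hydration(d, p) /
                 bare_pressure_hydration(d + p$lam, p),
               rep(exp(1), 3))
  expect_equal(bare_pressure_vdw(10, p), -2.1645e5, tolerance = 1e-4)
  expect_lt(bare_pressure_vdw(25, p), 0)
  # cubic decay: |P(2d)| = |P(d)|/8
  expect_equal(bare_pressure_vdw(24, p), bare_pressure_vdw(12, p) / 8)
  p0 <- interaction_params(A = 10^8.3, lam = 1.37, H = 0)
  expect_equal(bare_pressure_vdw(10, p0), 0)
  expect_error(bare_pressure_vdw(0, p), "positive")
  expect_error(bare_pressure_hydration(-2, p), "non-negative")
})

test_that("hydration pressure is the exact derivative of the potential term", {
  p <- interaction_params(A = 10^8.3, lam = 1.37, H = 0, steric = FALSE)
  d <- seq(2, 30, by = 0.5)
  eps <- 1e-5
  # -dPhi/da in zJ/A^3, converted to Pa (1 zJ/A^3 = 1e9 Pa)
  num <- -(bare_potential(d + eps, p) - bare_potential(d - eps, p)) / (2 * eps)
  expect_equal(num * 1e9, bare_pressure_hydration(d, p), tolerance = 1e-8)
})

test_that("zero of the bare pressure agrees with a dense grid scan", {
  p <- interaction_params(A = 10^8.3, lam = 1.37, H = 4.08)
  root <- bare_pressure_root(p)
  expect_true(is.finite(root))
  grid <- seq(2, 60, by = 1e-4)
  v <- bare_pressure_total(grid, p)
  i <- which(v[-1] * v[-length(v)] < 0)[1]
  expect_equal(root, grid[i], tolerance = 1e-3)
  # with fluctuations switched off the bare balance sits inside 5..15 A
  expect_gt(root, 5)
  expect_lt(root, 15)
})

test_that("parameter validation enforces physical invariants", {
  expect_error(interaction_params(A = -1, lam = 1.4, H = 4), "positive")
  expect_error(interaction_params(A = 1e8, lam = 0, H = 4), "positive")
  expect_error(interaction_params(A = 1e8, lam = 1.4, H = 4, a_cut = 0),
               "positive")
  p <- interaction_params(A = 1e8, lam = 1.4, H = 4, steric = FALSE)
  expect_identical(bare_pressure_steric(5, p), 0)
})
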