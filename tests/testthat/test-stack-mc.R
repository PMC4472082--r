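## Spectral bending energy oracle in R: FFT of the displacement field and
## the discrete-Laplacian eigenvalues q-hat^2 = (4/h^2)(sin^2 + sin^2).
spectral_bend_R <- function(u_row, N, L, Kc) {
  m <- matrix(u_row, N, N, byrow = TRUE)  # [x, y], site index s = x*N + y
  uh <- stats::fft(m) / N^2
  j <- 0:(N - 1)
  h <- L / N
  q2 <- (4 / h^2) * outer(sin(pi * j / N)^2, sin(pi * j / N)^2, "+")
  (Kc / 2) * L^2 * sum(q2^2 * Mod(uh)^2)
}

test_that("configuration validation enforces the stack invariants", {
  expect_error(sim_config(K_c = 44, P = 0, N = 3), "N must be")
  expect_error(sim_config(K_c = 44, P = 0, M = 1), "M must be")
  expect_error(sim_config(K_c = 0, P = 0), "K_c must be")
  expect_error(sim_config(K_c = 44, P = -5), "non-negative")
  cfg <- sim_config(K_c = 44, P = 0)
  expect_equal(cfg$L, 700)
  expect_equal(cfg$M, 8)
  expect_equal(cfg$n_equil, 3000L)
  expect_equal(cfg$n_collect, 10000L)
  expect_equal(cfg$T, 293.15)
})

test_that("total energy reproduces flat-stack limits", {
  N <- 6; M <- 4; L <- 700
  cfg <- sim_config(K_c = 44, P = 0, N = N, M = M, L = L)
  u <- matrix(0, M, N^2)
  # flat, non-interacting, zero pressure
  pot0 <- lamstack:::pot_list(NULL, type = "dlvo", hard_wall = TRUE)
  pot0$A <- 0; pot0$H <- 0; pot0$steric <- FALSE
  expect_equal(total_energy(u, 10, cfg, pot = pot0), 0)
  # flat at uniform separation d: interaction = M * L^2 * Phi(d)
  p <- ld_params()
  d <- 12
  e <- total_energy(u, d, cfg, p)
  expect_equal(e, M * L^2 * bare_potential(d, p), tolerance = 1e-12)
  # enthalpy term: P * M * L^2 * abar (in zJ)
  cfgP <- sim_config(K_c = 44, P = 2e5, N = N, M = M, L = L)
  expect_equal(total_energy(u, d, cfgP, p) - e,
               2e5 * M * L^2 * d * 1e-9, tolerance = 1e-9)
  # interpenetration is forbidden
  u2 <- u; u2[2, ] <- -15
  expect_identical(total_energy(u2, 10, cfg, p), Inf)
})

test_that("spectral and real-space bending energies agree on random states", {
  set.seed(1)
  N <- 8; M <- 3; L <- 700; Kc <- 44
  cfg <- sim_config(K_c = Kc, P = 0, N = N, M = M, L = L)
  pot0 <- lamstack:::pot_list(NULL, type = "dlvo", hard_wall = TRUE)
  pot0$A <- 0; pot0$H <- 0; pot0$steric <- FALSE
  for (r in 1:5) {
    u <- matrix(rnorm(M * N^2, sd = 2), M, N^2)
    e_real <- total_energy(u, 200, cfg, pot = pot0)  # large abar: no contact
    e_spec <- sum(vapply(seq_len(M), function(m)
      spectral_bend_R(u[m, ], N, L, Kc), numeric(1)))
    expect_equal(e_real, e_spec, tolerance = 1e-6)
  }
})

test_that("same seed gives bit-identical observables", {
  o1 <- small_sim(seed = 77)
  cfg <- sim_config(K_c = 44, P = 1e5, N = 6, M = 4, n_equil = 600,
                    n_collect = 2500, seed = 77)
  o2 <- suppressWarnings(run_simulation(cfg, ld_params()))
  expect_identical(o1$d_W, o2$d_W)
  expect_identical(o1$delta2, o2$delta2)
  expect_identical(o1$archive$abar, o2$archive$abar)
})

test_that("incremental energy bookkeeping matches from-scratch recomputation", {
  o <- small_sim()
  expect_lt(o$book_dev, 1e-6)
})

test_that("observables are gauge invariant under a uniform shift of all u_m", {
  o <- small_sim()
  u <- o$final_u
  cfg <- o$cfg
  gaps <- function(u) {
    M <- nrow(u)
    do.call(rbind, lapply(seq_len(M), function(m)
      u[(m %% M) + 1, ] - u[m, ] + o$final_abar))
  }
  expect_equal(gaps(u + 3.7), gaps(u), tolerance = 1e-12)
  p <- ld_params()
  expect_equal(total_energy(u + 3.7, o$final_abar, cfg, p),
               total_energy(u, o$final_abar, cfg, p), tolerance = 1e-9)
})

test_that("T -> 0 with a flat start at the bare minimum stays there", {
  p <- ld_params()
  a_min <- bare_pressure_root(p)  # minimum of Phi: P_bare(a) = 0
  cfg <- sim_config(K_c = 44, P = 0, N = 6, M = 4, T = 1e-4,
                    n_equil = 100, n_collect = 500, seed = 5, abar0 = a_min)
  o <- suppressWarnings(run_simulation(cfg, p))
  # step adaptation keeps proposing k_BT-scale wiggles, so "stays at the
  # minimum" means displacements of order sqrt(kT/curvature) ~ 1e-3 A
  expect_equal(o$d_W, a_min, tolerance = 1e-4)
  expect_lt(o$delta2, 1e-4)
})

test_that("harmonic confinement reproduces the closed-form Gaussian mode sum", {
  Kc <- 44; L <- 700; N <- 8; M <- 8; B <- 2e5; a0 <- 20
  pot <- lamstack:::pot_list(NULL, type = "harmonic", hard_wall = FALSE,
                             B = B, a0 = a0)
  cfg <- sim_config(K_c = Kc, P = 0, N = N, M = M, n_equil = 800,
                    n_collect = 5000, seed = 7, fix_abar = TRUE, abar0 = a0)
  o <- suppressWarnings(run_simulation(cfg, pot = pot))
  exact <- harmonic_delta2_exact(Kc, B, L, N, M)
  expect_lt(abs(o$delta2 - exact), 3 * o$se_delta2)
  expect_equal(o$d_W, a0)  # abar frozen
})

test_that("frozen-field spacing distribution matches direct quadrature", {
  ip <- interaction_params(A = 10^7.5, lam = 1.37, H = 4.0)
  P <- 5e5
  cfg <- sim_config(K_c = 44, P = P, N = 4, M = 2, n_equil = 1500,
                    n_collect = 30000, seed = 3, freeze_u = TRUE,
                    abar0 = 8, record_every = 2)
  o <- suppressWarnings(run_simulation(cfg, ip))
  # with u frozen flat, the abar marginal is 1-D:
  # E(a) = M L^2 Phi(a) + P M L^2 a
  kT <- kBT_zJ(cfg$T)
  E <- function(a) 2 * 700^2 * bare_potential(a, ip) + P * 1e-9 * 2 * 700^2 * a
  a <- seq(0.01, 40, length.out = 8000)
  w <- exp(-(E(a) - min(E(a))) / kT)
  w <- w / sum(w)
  expect_lt(abs(o$d_W - sum(w * a)), 3 * o$se_dW)
})

test_that("step adaptation lands collection acceptance in a sane band", {
  o <- small_sim(seed = 21)
  expect_gt(o$acc_mode, 0.3)
  expect_lt(o$acc_mode, 0.7)
  expect_gt(o$acc_abar, 0.2)
  expect_lt(o$acc_abar, 0.8)
})

test_that("DOMC step adaptation agrees with ARM on the same system", {
  cfg_arm <- sim_config(K_c = 44, P = 1e5, N = 6, M = 4, n_equil = 600,
                        n_collect = 2500, seed = 31)
  cfg_domc <- sim_config(K_c = 44, P = 1e5, N = 6, M = 4, n_equil = 600,
                         n_collect = 2500, seed = 32, step_adapt = "DOMC")
  o_arm <- suppressWarnings(run_simulation(cfg_arm, ld_params()))
  o_domc <- suppressWarnings(run_simulation(cfg_domc, ld_params()))
  expect_gt(o_domc$acc_mode, 0.25)
  expect_lt(o_domc$acc_mode, 0.75)
  se <- sqrt(o_arm$se_dW^2 + o_domc$se_dW^2)
  expect_lt(abs(o_arm$d_W - o_domc$d_W), 4 * se)
})

test_that("compression under pressure: d_W and Delta decrease with P", {
  Ps <- c(1e5, 1e6, 5e6)
  obs <- lapply(seq_along(Ps), function(i) small_sim(seed = 40 + i, P = Ps[i]))
  dW <- vapply(obs, `[[`, numeric(1), "d_W")
  se <- vapply(obs, `[[`, numeric(1), "se_dW")
  D2 <- vapply(obs, `[[`, numeric(1), "delta2")
  seD <- vapply(obs, `[[`, numeric(1), "se_delta2")
  expect_true(all(diff(dW) < 2 * sqrt(se[-1]^2 + se[-3]^2)))
  expect_true(all(diff(D2) < 2 * sqrt(seD[-1]^2 + seD[-3]^2)))
})
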