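## Shared fixtures for the test suite. Heavy simulation products used by
## several test blocks are computed once per run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## Table-parameter sets for the two coexisting phases
ld_params <- function() interaction_params(A = 10^8.3, lam = 1.37, H = 4.08)
lo_params <- function() interaction_params(A = 10^8.1, lam = 1.74, H = 4.15)

## A small, quick archive-producing simulation (liquid-disordered-like)
small_sim <- function(seed = 11, P = 1e5, N = 6, M = 4,
                      n_equil = 600, n_collect = 2500) {
  cfg <- sim_config(K_c = 44, P = P, N = N, M = M, n_equil = n_equil,
                    n_collect = n_collect, seed = seed)
  suppressWarnings(run_simulation(cfg, ld_params()))
}

## Hard-wall-only potential hook (no hydration, no vdW, no steric)
hard_wall_pot <- function() {
  pot <- lamstack:::pot_list(NULL, type = "dlvo", hard_wall = TRUE)
  pot$A <- 0
  pot$H <- 0
  pot$steric <- FALSE
  pot
}

## Closed-form Delta^2 for the harmonic-confinement Gaussian model with
## fixed mean spacing: discrete mode sum over the M x N x N lattice.
harmonic_delta2_exact <- function(K_c, B_Pa_per_A, L, N, M, T_K = 293.15) {
  kT <- kBT_zJ(T_K)
  h <- L / N
  Bp <- B_Pa_per_A * 1e-9  # zJ / A^4
  j <- 0:(N - 1)
  q2 <- (4 / h^2) * outer(sin(pi * j / N)^2, sin(pi * j / N)^2, "+")
  q4 <- as.numeric(q2^2)
  m2 <- 4 * sin(pi * (0:(M - 1)) / M)^2
  tot <- 0
  for (p in seq_along(m2)) {
    cc <- K_c * q4 + Bp * m2[p]
    ok <- cc > 0
    tot <- tot + sum(m2[p] * kT / (L^2 * M * cc[ok]))
  }
  tot
}
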