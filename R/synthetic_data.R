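## Synthetic osmotic-stress datasets with known ground truth, so that the
## whole analysis chain (simulation, reweighting, fitting, decomposition)
## is testable without experimental data.

#' Specify a synthetic osmotic-stress dataset
#'
#' The defaults emulate a typical osmotic-stress experiment on a
#' liquid-disordered phase: 8-12 pressure points spanning zero to a few
#' MPa, water spacings from about 5 to 17 A, fluctuation amplitudes of
#' 2-7 A, 6% relative pressure uncertainty, 0.5 A spacing uncertainty and
#' 5% relative fluctuation uncertainty.
#'
#' @param logA,lam,K_c ground-truth parameters: log10 hydration amplitude
#'   (A in Pa), hydration decay length (A), bending rigidity (zJ).
#' @param H Hamaker coefficient (zJ), fixed (not a fit parameter).
#' @param pressures pressure grid (Pa), non-negative.
#' @param U_P_rel relative pressure uncertainty (default 0.06).
#' @param U_dW absolute spacing uncertainty (A, default 0.5).
#' @param U_Delta_rel relative fluctuation uncertainty (default 0.05).
#' @param generator `"simulator"` (stack Monte Carlo; the reference
#'   generator) or `"meanfield"` (fast soft-confinement surrogate; for
#'   quick tests and initialization only).
#' @param sim_opts [sim_config] arguments for the simulator generator.
#' @param seed RNG seed for both the simulations and the noise.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(logA = 8.3, lam = 1.37, K_c = 44, H = 4.08,
                           pressures = c(0, 3e4, 1e5, 3e5, 1e6, 2e6, 5e6, 1e7),
                           U_P_rel = 0.06, U_dW = 0.5, U_Delta_rel = 0.05,
                           generator = c("simulator", "meanfield"),
                           sim_opts = list(), seed = 1L) {
  generator <- match.arg(generator)
  if (any(pressures < 0)) stop("pressures must be non-negative")
  pressures <- sort(pressures)
  if (U_P_rel < 0 || U_dW < 0 || U_Delta_rel < 0) {
    stop("noise levels must be non-negative")
  }
  structure(list(logA = logA, lam = lam, K_c = K_c, H = H,
                 pressures = pressures, U_P_rel = U_P_rel, U_dW = U_dW,
                 U_Delta_rel = U_Delta_rel, generator = generator,
                 sim_opts = sim_opts, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic osmotic-stress dataset
#'
#' Computes noise-free (d_W, Delta) at each pressure with the chosen
#' generator, then adds independent Gaussian noise at the specified levels
#' and jitters the pressures by their relative uncertainty. The ground
#' truth is returned alongside the dataset.
#'
#' @param spec a [synthetic_spec].
#' @return A list with `dataset` (a [stress_dataset]), `truth` (named list
#'   of the generating parameters) and `noise_free` (the pre-noise table).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ip <- interaction_params(A = 10^spec$logA, lam = spec$lam, H = spec$H)
  P <- spec$pressures

  if (spec$generator == "simulator") {
    iso <- simulate_isotherm(P, list(logA = spec$logA, lam = spec$lam,
                                     K_c = spec$K_c),
                             template = ip, sim_opts = spec$sim_opts,
                             seed = spec$seed)
    d_W <- iso$table$d_W
    Delta <- iso$table$Delta
    U_sim_dW <- iso$table$U_sim_dW
    U_sim_Delta <- iso$table$U_sim_Delta
  } else {
    d_W <- vapply(P, meanfield_spacing, numeric(1), p = ip, K_c = spec$K_c)
    Delta <- vapply(d_W, meanfield_delta, numeric(1), p = ip, K_c = spec$K_c)
    U_sim_dW <- rep(0, length(P))
    U_sim_Delta <- rep(0, length(P))
  }
  noise_free <- data.frame(P_Pa = P, dW_A = d_W, Delta_A = Delta)

  set.seed(spec$seed)
  P_obs <- pmax(P * (1 + spec$U_P_rel * stats::rnorm(length(P))), 0)
  dW_obs <- d_W + spec$U_dW * stats::rnorm(length(P))
  Delta_obs <- pmax(Delta * (1 + spec$U_Delta_rel * stats::rnorm(length(P))),
                    1e-3)
  U_dW_tot <- sqrt(spec$U_dW^2 + U_sim_dW^2)
  U_Delta_tot <- sqrt((spec$U_Delta_rel * Delta)^2 + U_sim_Delta^2)
  if (spec$U_dW == 0) U_dW_tot <- pmax(U_dW_tot, 1e-6)
  if (spec$U_Delta_rel == 0) U_Delta_tot <- pmax(U_Delta_tot, 1e-6)

  dataset <- stress_dataset(P_obs, pmax(dW_obs, 0.5), Delta_obs,
                            U_dW = U_dW_tot, U_Delta = U_Delta_tot,
                            U_P_rel = max(spec$U_P_rel, 1e-6))
  list(dataset = dataset,
       truth = list(logA = spec$logA, lam = spec$lam, K_c = spec$K_c,
                    H = spec$H, generator = spec$generator,
                    seed = spec$seed),
       noise_free = noise_free)
}
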