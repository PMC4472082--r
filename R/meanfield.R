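## Fast mean-field (soft-confinement) surrogate for the equation of state.
##
## Used ONLY to initialize simulations and to generate cheap synthetic
## datasets: the undulation pressure is approximated by the soft-confinement
## closed form with decay length 2*lambda, which the explicit stack
## simulation supersedes everywhere results matter. Mean-field additivity of
## bare and fluctuation pressures is precisely the approximation the
## simulation avoids, so this surrogate must never stand in for it.

#' Mean-field undulation pressure
#'
#' Soft-confinement estimate for a membrane of rigidity `K_c` confined by
#' the hydration potential: fluctuations in the local harmonic well of
#' curvature \eqn{\Phi''_{hyd}} contribute a free energy
#' \eqn{(k_BT/8)\sqrt{\Phi''/K_c}} per unit area, giving
#' \deqn{P_{und}(d) = \frac{k_B T}{16\lambda}\sqrt{\frac{A}{\lambda K_c}}
#'       \, e^{-d/2\lambda},}
#' i.e. an exponential with decay length twice the hydration decay length.
#'
#' @param d_W water spacing(s), A.
#' @param p an [interaction_params] object.
#' @param K_c bending rigidity (zJ).
#' @param T_K temperature (K).
#' @return Pressure in Pa.
#' @export
meanfield_pressure_und <- function(d_W, p, K_c, T_K = 293.15) {
  kT_J <- kBT_zJ(T_K) * 1e-21
  lam_m <- p$lam * 1e-10
  Kc_J <- K_c * 1e-21
  A_und <- kT_J / (16 * lam_m) * sqrt(p$A / (lam_m * Kc_J))
  A_und * exp(-d_W / (2 * p$lam))
}

#' Mean-field equilibrium spacing
#'
#' Solves \eqn{P_{hyd} + P_{vdW} + P_{st} + P_{und}^{mf} = P} for the water
#' spacing. Used as a starting point for simulations and by the fast
#' synthetic-data generator.
#'
#' @param P applied osmotic pressure (Pa).
#' @inheritParams meanfield_pressure_und
#' @return Water spacing in A.
#' @export
meanfield_spacing <- function(P, p, K_c, T_K = 293.15) {
  f <- function(d) {
    bare_pressure_total(d, p) + meanfield_pressure_und(d, p, K_c, T_K) - P
  }
  lo <- 1
  hi <- 200
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  d <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  if (d < 2 * p$lam) {
    warning("mean-field surrogate evaluated at very high pressure; ",
            "outside its range of validity")
  }
  d
}

#' Mean-field fluctuation amplitude
#'
#' Harmonic (Gaussian) estimate
#' \eqn{\Delta^2 = k_B T / (8\sqrt{B K_c})} with `B` the curvature of the
#' repulsive part of the bare potential at spacing `d_W`.
#'
#' @inheritParams meanfield_pressure_und
#' @return Delta in A.
#' @export
meanfield_delta <- function(d_W, p, K_c, T_K = 293.15) {
  A_zJ <- p$A * lamstack_constants$pa_a3_to_zj
  B <- A_zJ / p$lam * exp(-d_W / p$lam)
  if (p$steric) {
    Ast_zJ <- p$A_st * lamstack_constants$pa_a3_to_zj
    B <- B + Ast_zJ / p$lam_st * exp(-d_W / p$lam_st)
  }
  d2 <- kBT_zJ(T_K) / (8 * sqrt(B * K_c))
  sqrt(d2)
}
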