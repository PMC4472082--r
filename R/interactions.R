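## Bare (fluctuation-free) interaction potentials and pressures between
## neighbouring membranes: exponential hydration repulsion, van der Waals
## attraction between semi-infinite planar layers, and a very short range
## steric repulsion that prevents unphysical collapse at sub-angstrom
## separations.

#' Bare interaction parameters between neighbouring membranes
#'
#' Bundles the constants of the bare (fluctuation-free) interaction potential
#' per unit area between two apposed membranes,
#' \deqn{\Phi(a) = A\lambda e^{-a/\lambda} - \frac{H}{12\pi \max(a, a_{cut})^2}
#'   + A_{st}\lambda_{st} e^{-a/\lambda_{st}},}
#' i.e. hydration repulsion of amplitude `A` and decay length `lam`, van der
#' Waals attraction with Hamaker coefficient `H`, and a steep steric
#' repulsion. The divergent van der Waals term is clamped below `a_cut`
#' (constant potential, zero force), which keeps the energy finite while
#' leaving the potential continuous at the cutoff.
#'
#' @param A hydration amplitude (Pa). Typically quoted as a power of ten,
#'   e.g. `10^8.3` Pa for a liquid-disordered phase.
#' @param lam hydration decay length (A); typically 1--2 A.
#' @param H Hamaker coefficient (zJ); e.g. 4.08 zJ (Ld) or 4.15 zJ (Lo).
#' @param A_st steric amplitude (Pa); default 3.6 GPa.
#' @param lam_st steric decay length (A); default 0.6 A.
#' @param a_cut separation below which the van der Waals term is clamped (A);
#'   default 1 A.
#' @param steric logical; include the steric term (default `TRUE`). It is
#'   unimportant at realistic parameters but kept for completeness.
#' @return An object of class `interaction_params`.
#' @export
interaction_params <- function(A, lam, H,
                               A_st = 3.6e9, lam_st = 0.6,
                               a_cut = 1.0, steric = TRUE) {
  stopifnot(is.numeric(A), is.numeric(lam), is.numeric(H),
            length(A) == 1L, length(lam) == 1L, length(H) == 1L)
  if (!(A > 0)) stop("hydration amplitude A must be positive")
  if (!(lam > 0)) stop("hydration decay length lam must be positive")
  if (A_st < 0) stop("steric amplitude A_st must be non-negative")
  if (!(lam_st > 0)) stop("steric decay length lam_st must be positive")
  if (!(a_cut > 0)) stop("vdW cutoff a_cut must be positive")
  structure(list(A = A, lam = lam, H = H, A_st = A_st, lam_st = lam_st,
                 a_cut = a_cut, steric = isTRUE(steric)),
            class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  cat("Bare interaction parameters:\n")
  cat(sprintf("  hydration:  A = %.4g Pa (10^%.3f), lambda = %.3f A\n",
              x$A, log10(x$A), x$lam))
  cat(sprintf("  van der Waals: H = %.3f zJ, cutoff a_cut = %.2f A\n",
              x$H, x$a_cut))
  if (x$steric) {
    cat(sprintf("  steric:     A_st = %.3g Pa, lambda_st = %.2f A\n",
                x$A_st, x$lam_st))
  } else {
    cat("  steric:     off\n")
  }
  invisible(x)
}

#' Bare interaction potential per unit area
#'
#' Evaluates the bare potential \eqn{\Phi(a)} (zJ/A^2) at separation `a`.
#' The van der Waals `1/a^2` term is evaluated at `max(a, a_cut)`, so the
#' potential tends to the finite value
#' \eqn{A\lambda + A_{st}\lambda_{st} - H/(12\pi a_{cut}^2)} as `a -> 0`
#' and to zero as `a -> Inf`.
#'
#' @param a separation(s) in A; must be non-negative.
#' @param p an [interaction_params] object.
#' @return Potential per unit area in zJ/A^2 (1 zJ/A^2 = 0.1 J/m^2).
#' @export
bare_potential <- function(a, p) {
  stopifnot(inherits(p, "interaction_params"))
  if (any(a < 0)) stop("separation a must be non-negative")
  A_zJ <- p$A * lamstack_constants$pa_a3_to_zj      # zJ / A^3
  v <- A_zJ * p$lam * exp(-a / p$lam)
  if (p$steric) {
    # beyond 50 decay lengths the sub-angstrom steric term is below double
    # precision; treated as exactly zero (kept identical in the MC core)
    Ast_zJ <- p$A_st * lamstack_constants$pa_a3_to_zj
    st <- ifelse(a < 50 * p$lam_st, Ast_zJ * p$lam_st * exp(-a / p$lam_st), 0)
    v <- v + st
  }
  ac <- pmax(a, p$a_cut)
  v - p$H / (12 * pi * ac^2)
}

#' Bare hydration pressure
#'
#' \eqn{P_{hyd}(d_W) = A e^{-d_W/\lambda}} in Pa, the negative derivative of
#' the hydration term of [bare_potential] with respect to separation.
#'
#' @param d_W water spacing(s) in A; non-negative.
#' @param p an [interaction_params] object.
#' @return Pressure in Pa.
#' @export
bare_pressure_hydration <- function(d_W, p) {
  stopifnot(inherits(p, "interaction_params"))
  if (any(d_W < 0)) stop("water spacing d_W must be non-negative")
  p$A * exp(-d_W / p$lam)
}

#' Bare van der Waals pressure
#'
#' \eqn{P_{vdW}(d_W) = -H/(6\pi d_W^3)} in Pa; attractive (negative) for
#' positive Hamaker coefficient.
#'
#' @param d_W water spacing(s) in A; strictly positive.
#' @param p an [interaction_params] object.
#' @return Pressure in Pa.
#' @export
bare_pressure_vdw <- function(d_W, p) {
  stopifnot(inherits(p, "interaction_params"))
  if (any(d_W <= 0)) stop("water spacing d_W must be positive")
  # H [zJ] / d^3 [A^3] = 1e-21 J / 1e-30 m^3 = 1e9 Pa
  -(p$H * 1e9) / (6 * pi * d_W^3)
}

#' Bare steric pressure
#'
#' \eqn{P_{st}(d_W) = A_{st} e^{-d_W/\lambda_{st}}} in Pa; zero when the
#' steric term is switched off.
#'
#' @inheritParams bare_pressure_hydration
#' @return Pressure in Pa.
#' @export
bare_pressure_steric <- function(d_W, p) {
  stopifnot(inherits(p, "interaction_params"))
  if (any(d_W < 0)) stop("water spacing d_W must be non-negative")
  if (!p$steric) return(rep(0, length(d_W)))
  p$A_st * exp(-d_W / p$lam_st)
}

#' Total bare pressure
#'
#' Sum of hydration, van der Waals and (optionally) steric bare pressures.
#'
#' @inheritParams bare_pressure_vdw
#' @return Pressure in Pa.
#' @export
bare_pressure_total <- function(d_W, p) {
  bare_pressure_hydration(d_W, p) + bare_pressure_vdw(d_W, p) +
    bare_pressure_steric(d_W, p)
}

#' Zero of the bare pressure
#'
#' Separation at which the bare (fluctuation-free) pressure
#' \eqn{P_{hyd} + P_{vdW} + P_{st}} vanishes, found by bisection on
#' `[lower, upper]`.
#'
#' @param p an [interaction_params] object.
#' @param lower,upper bracketing interval in A.
#' @return Separation in A, or `NA` if no sign change inside the bracket.
#' @export
bare_pressure_root <- function(p, lower = 2, upper = 60) {
  f <- function(a) bare_pressure_total(a, p)
  if (f(lower) * f(upper) > 0) return(NA_real_)
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}
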