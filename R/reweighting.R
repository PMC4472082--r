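## Histogram reweighting: estimate observables (and their parameter
## derivatives) at perturbed parameters from samples collected at the
## simulated parameters, without running new simulations.
##
## Each archived sample carries the mean spacing, the spatial mean of the
## squared local separation, the spectral bending sum S (bending energy =
## K_c * S) and a histogram of local separations. The energy difference
## between parameter sets is therefore computable per sample: the bending
## part from S, the hydration (and steric) part by quadrature over the
## histogram. The van der Waals term, the hard wall and the enthalpy term do
## not depend on the fit parameters and cancel in the weights.

## Hydration (+ steric) interaction energy per sample from the histogram,
## for arbitrary (A, lam). Returns a vector over samples, in zJ.
archive_hyd_energy <- function(archive, A, lam) {
  cfg <- archive$cfg
  h2 <- (cfg$L / cfg$N)^2
  A_zJ <- A * lamstack_constants$pa_a3_to_zj
  kern <- A_zJ * lam * exp(-archive$bin_centers / lam)
  if (isTRUE(archive$pot$steric)) {
    Ast_zJ <- archive$pot$A_st * lamstack_constants$pa_a3_to_zj
    lst <- archive$pot$lam_st
    kern <- kern + ifelse(archive$bin_centers < 50 * lst,
                          Ast_zJ * lst * exp(-archive$bin_centers / lst), 0)
  }
  h2 * as.numeric(crossprod(archive$hist, kern))
}

#' Reweight archived samples to perturbed parameters
#'
#' Computes the observables \eqn{d_W} and \eqn{\Delta^2} at parameters
#' `lambda_new` = (A, lam, K_c) from an archive collected at the archive's
#' own parameters, using weights
#' \eqn{w_s \propto \exp(-[E(\Lambda'; s) - E(\Lambda; s)]/k_BT)}. Both
#' energies are evaluated from the same archived summaries (histogram
#' quadrature for the hydration term, stored spectral sum for bending), so
#' binning errors cancel to first order. The perturbation must stay inside
#' the trust region: if the effective sample size falls below
#' `min_ess_frac` of the number of samples, the call refuses and the caller
#' must re-simulate.
#'
#' @param archive a `sample_archive` from [run_simulation].
#' @param lambda_new named list or vector with `A` (Pa), `lam` (A),
#'   `K_c` (zJ).
#' @param min_ess_frac minimum effective sample size as a fraction of the
#'   archived samples (default 0.2).
#' @return A list with `d_W`, `delta2`, `ess`, `n` and the weights.
#' @export
reweight_observable <- function(archive, lambda_new, min_ess_frac = 0.2) {
  stopifnot(inherits(archive, "sample_archive"))
  lambda_new <- as.list(lambda_new)
  stopifnot(all(c("A", "lam", "K_c") %in% names(lambda_new)))
  p0 <- archive$params
  kT <- kBT_zJ(archive$cfg$T)

  dE <- (lambda_new$K_c - p0$K_c) * archive$sbend
  if (lambda_new$A != p0$A || lambda_new$lam != p0$lam) {
    dE <- dE + archive_hyd_energy(archive, lambda_new$A, lambda_new$lam) -
      archive_hyd_energy(archive, p0$A, p0$lam)
  }
  lw <- -dE / kT
  lw <- lw - max(lw)
  w <- exp(lw)
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  n <- length(w)
  if (ess < min_ess_frac * n) {
    stop(sprintf(paste0("effective sample size %.0f below %.0f%% of %d ",
                        "samples: perturbation outside the reweighting ",
                        "trust region; re-simulate"),
                 ess, 100 * min_ess_frac, n))
  }
  d_W <- sum(w * archive$abar)
  delta2 <- sum(w * archive$s2) - d_W^2
  list(d_W = d_W, delta2 = delta2, ess = ess, n = n, weights = w)
}

#' Parameter derivatives of the observables by reweighting
#'
#' Central finite differences of the reweighted observables with relative
#' step `rel_step` (default 1e-2) in one of the fit parameters `"A"`,
#' `"logA"`, `"lam"` or `"K_c"`. For `"logA"` the amplitude is perturbed by
#' `rel_step` relatively and the difference quotient taken against
#' log10(A), matching the log-scale parameterization of the fit. Requests
#' for parameters that are not fit parameters (e.g. the Hamaker
#' coefficient) are rejected.
#'
#' @param archive a `sample_archive`.
#' @param which one of `"A"`, `"logA"`, `"lam"`, `"K_c"`.
#' @param rel_step relative finite-difference step.
#' @return Named numeric vector with `d_dW` and `d_delta2`, the derivatives
#'   of d_W and Delta^2 with respect to the requested parameter.
#' @export
observable_derivative <- function(archive, which, rel_step = 1e-2) {
  stopifnot(inherits(archive, "sample_archive"))
  valid <- c("A", "logA", "lam", "K_c")
  if (!which %in% valid) {
    stop(sprintf("'%s' is not a fit parameter (one of %s)", which,
                 paste(valid, collapse = ", ")))
  }
  p0 <- archive$params
  perturb <- function(fac_A = 1, fac_lam = 1, fac_Kc = 1) {
    reweight_observable(archive, list(A = p0$A * fac_A,
                                      lam = p0$lam * fac_lam,
                                      K_c = p0$K_c * fac_Kc))
  }
  # the admissible perturbation shrinks with system size (the energy
  # difference per sample grows extensively); halve the step until the
  # effective sample size is inside the trust region
  eval_pair <- function(s) {
    if (which %in% c("A", "logA")) {
      list(up = perturb(fac_A = 1 + s), dn = perturb(fac_A = 1 - s),
           dx = if (which == "A") 2 * s * p0$A else
             log10(1 + s) - log10(1 - s))
    } else if (which == "lam") {
      list(up = perturb(fac_lam = 1 + s), dn = perturb(fac_lam = 1 - s),
           dx = 2 * s * p0$lam)
    } else {
      list(up = perturb(fac_Kc = 1 + s), dn = perturb(fac_Kc = 1 - s),
           dx = 2 * s * p0$K_c)
    }
  }
  s <- rel_step
  pair <- NULL
  for (halve in 1:8) {
    pair <- tryCatch(eval_pair(s), error = function(e) {
      if (grepl("effective sample size", conditionMessage(e))) NULL else stop(e)
    })
    if (!is.null(pair)) break
    s <- s / 2
  }
  if (is.null(pair)) stop("no admissible finite-difference step found")
  c(d_dW = (pair$up$d_W - pair$dn$d_W) / pair$dx,
    d_delta2 = (pair$up$delta2 - pair$dn$delta2) / pair$dx)
}
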