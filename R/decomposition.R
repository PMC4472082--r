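## Partition of the total osmotic pressure into hydration, van der Waals
## and undulation components, the effective undulation decay length, and
## the stiff-ring consistency check relating bending and stretching moduli.

#' Decompose an isotherm into pressure components
#'
#' Given total-pressure/spacing pairs `(P, d_W)` (from simulation or
#' experiment) and the bare interaction constants, subtracts the bare
#' pressures pointwise, \eqn{P_{und} = P - P_{hyd} - P_{vdW} - P_{st}}, fits
#' \eqn{P_{und} = A_{und} e^{-d_W/\lambda_{und}}} by unweighted log-linear
#' least squares restricted to large separations (`d_W >= fit_min_dW`,
#' default 14 A, where the undulation pressure is closest to a single
#' exponential), and locates the crossing separation where the hydration
#' and undulation pressures are equal, by monotone cubic interpolation of
#' their difference.
#'
#' Points with non-positive `P_und` are excluded from the log-fit with a
#' warning; if all usable `P_und` are negligible relative to the bare
#' pressures the exponential fit is refused.
#'
#' @param P total osmotic pressures (Pa).
#' @param d_W water spacings (A), same length; need not be sorted.
#' @param p an [interaction_params] object.
#' @param fit_min_dW lower spacing bound of the exponential fit (A).
#' @return An object of class `pressure_decomposition`: a `grid` data.frame
#'   with `d_W`, `P_total`, `P_hyd`, `P_vdW`, `P_st`, `P_und`; fit results
#'   `A_und` (Pa), `lam_und` (A) with standard errors, `n_fit`; and
#'   `d_cross` (A, `NA` if no crossing).
#' @export
decompose_pressure <- function(P, d_W, p, fit_min_dW = 14) {
  stopifnot(length(P) == length(d_W), inherits(p, "interaction_params"))
  ord <- order(d_W)
  d_W <- d_W[ord]
  P <- P[ord]
  P_hyd <- bare_pressure_hydration(d_W, p)
  P_vdW <- bare_pressure_vdw(d_W, p)
  P_st <- bare_pressure_steric(d_W, p)
  P_und <- P - P_hyd - P_vdW - P_st
  grid <- data.frame(d_W = d_W, P_total = P, P_hyd = P_hyd, P_vdW = P_vdW,
                     P_st = P_st, P_und = P_und)

  # undulation negligible against the bare scale -> no meaningful fit
  scale <- pmax(abs(P_hyd) + abs(P_vdW) + abs(P), .Machine$double.eps)
  A_und <- lam_und <- se_A_und <- se_lam_und <- NA_real_
  n_fit <- 0L
  if (all(abs(P_und) / scale < 1e-9)) {
    warning("undulation pressure is zero within tolerance; exponential fit refused")
  } else {
    use <- d_W >= fit_min_dW & P_und > 0
    if (any(d_W >= fit_min_dW & P_und <= 0)) {
      warning("excluding points with non-positive undulation pressure from the log-fit")
    }
    n_fit <- sum(use)
    if (n_fit < 2) {
      warning("fewer than 2 usable points with d_W >= ", fit_min_dW,
              " A; undulation decay fit not performed")
    } else {
      fm <- stats::lm(log(P_und[use]) ~ d_W[use])
      sl <- stats::coef(fm)[2]
      lam_und <- -1 / sl
      A_und <- exp(stats::coef(fm)[1])
      sm <- summary(fm)$coefficients
      if (n_fit > 2) {
        se_lam_und <- sm[2, 2] / sl^2
        se_A_und <- A_und * sm[1, 2]
      }
    }
  }

  # crossing of hydration and undulation pressures
  d_cross <- NA_real_
  diffs <- P_hyd - P_und
  sgn <- sign(diffs)
  cross_idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross_idx) > 0 && length(d_W) >= 3) {
    f <- stats::splinefun(d_W, diffs, method = "monoH.FC")
    i <- cross_idx[1]
    d_cross <- stats::uniroot(f, c(d_W[i], d_W[i + 1]), tol = 1e-8)$root
  } else if (length(cross_idx) > 0) {
    i <- cross_idx[1]
    d_cross <- d_W[i] + (d_W[i + 1] - d_W[i]) *
      diffs[i] / (diffs[i] - diffs[i + 1])
  }

  structure(list(grid = grid, A_und = unname(A_und),
                 lam_und = unname(lam_und),
                 se_A_und = unname(se_A_und), se_lam_und = unname(se_lam_und),
                 n_fit = n_fit, fit_min_dW = fit_min_dW, d_cross = d_cross),
            class = "pressure_decomposition")
}

#' @export
print.pressure_decomposition <- function(x, ...) {
  cat("Pressure decomposition (P = P_hyd + P_vdW + P_st + P_und):\n")
  cat(sprintf("  %d grid points, d_W in [%.2f, %.2f] A\n",
              nrow(x$grid), min(x$grid$d_W), max(x$grid$d_W)))
  if (is.finite(x$lam_und)) {
    cat(sprintf("  P_und fit (d_W >= %.0f A, %d pts): A_und = %.3g Pa, lambda_und = %.3f A\n",
                x$fit_min_dW, x$n_fit, x$A_und, x$lam_und))
  } else {
    cat("  undulation decay fit: not available\n")
  }
  if (is.finite(x$d_cross)) {
    cat(sprintf("  hydration/undulation crossing at d_W = %.2f A\n", x$d_cross))
  }
  invisible(x)
}

#' Stiff-ring size from bending and stretching moduli
#'
#' For cholesterol-rich membranes the bending rigidity can be related to
#' the area extension modulus through a rigid segment (the cholesterol
#' ring) of effective thickness \eqn{\delta'}, via
#' \eqn{\delta'^2 = 12 K_c / K_A}.
#'
#' @param K_c bending rigidity (zJ).
#' @param K_A area extension modulus (mN/m).
#' @return \eqn{\delta'} in A.
#' @export
ring_size <- function(K_c, K_A) {
  if (any(K_c <= 0) || any(K_A <= 0)) stop("K_c and K_A must be positive")
  # sqrt(12 * Kc[J] / KA[N/m]) in m, converted to A
  sqrt(12 * (K_c * 1e-21) / (K_A * 1e-3)) * 1e10
}
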