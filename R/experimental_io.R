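## Conversion of SAXS-derived lamellar quantities (repeat distance d,
## Caille parameter eta, bilayer thickness d_B) into the (P, d_W, Delta)
## dataset consumed by the fit.

#' Fluctuation amplitude from the Caille parameter
#'
#' The lamellar line-shape exponent eta relates to the mean-square spacing
#' fluctuation via \eqn{\Delta^2 = \eta d^2 / \pi^2}.
#'
#' @param eta Caille parameter (dimensionless, >= 0).
#' @param d lamellar repeat distance (A, > 0).
#' @return Delta in A.
#' @export
caille_to_delta <- function(eta, d) {
  if (any(eta < 0)) stop("eta must be non-negative")
  if (any(d <= 0)) stop("d must be positive")
  d * sqrt(eta) / pi
}

#' Osmotic thickening of the bilayer
#'
#' Under osmotic stress the bilayer thickens slightly because its area is
#' compressed; with area extension modulus `K_A`,
#' \deqn{d_B(P) = d_B(0)\,\frac{K_A + P\,d(P)}{K_A + P\,d_B(0)}.}
#'
#' @param d_B0 zero-stress (steric) bilayer thickness (A).
#' @param K_A area extension modulus (mN/m).
#' @param P osmotic pressure (Pa).
#' @param d_at_P lamellar repeat distance at pressure `P` (A).
#' @return d_B(P) in A.
#' @export
osmotic_thickening <- function(d_B0, K_A, P, d_at_P) {
  if (any(K_A <= 0)) stop("K_A must be positive")
  if (any(P < 0)) stop("P must be non-negative")
  if (any(d_at_P < d_B0)) stop("repeat distance below bilayer thickness")
  # K_A in mN/m = 1e-3 N/m; P*d in Pa*A = 1e-10 N/m
  KA_SI <- K_A * 1e-3
  d_B0 * (KA_SI + P * d_at_P * 1e-10) / (KA_SI + P * d_B0 * 1e-10)
}

#' Build a stress dataset from lamellar SAXS records
#'
#' For each record, computes the pressure-thickened bilayer thickness, the
#' water spacing \eqn{d_W = d - d_B(P)} and the fluctuation amplitude from
#' the Caille parameter, with first-order (delta-method) propagation of the
#' uncertainties in `d` and `eta`. Records implying a non-positive water
#' layer are rejected with a message.
#'
#' @param records a `data.frame` with columns `P_Pa`, `d_A`, `eta`,
#'   `U_d_A`, `U_eta`, `d_B0_A`, `K_A_mN_m`, and optionally `U_dB0_A`
#'   (default 0) and `U_P_rel` (default 0.06).
#' @return A [stress_dataset]. Empty input yields an empty (but valid)
#'   dataset.
#' @export
build_dataset <- function(records) {
  need <- c("P_Pa", "d_A", "eta", "U_d_A", "U_eta", "d_B0_A", "K_A_mN_m")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) {
    out <- data.frame(P_Pa = numeric(0), dW_A = numeric(0),
                      U_dW_A = numeric(0), Delta_A = numeric(0),
                      U_Delta_A = numeric(0), U_P_rel = numeric(0))
    class(out) <- c("stress_dataset", "data.frame")
    return(out)
  }
  if (is.null(records$U_dB0_A)) records$U_dB0_A <- 0
  if (is.null(records$U_P_rel)) records$U_P_rel <- 0.06

  ok <- records$d_A > records$d_B0_A
  d_B <- rep(NA_real_, nrow(records))
  d_B[ok] <- osmotic_thickening(records$d_B0_A[ok], records$K_A_mN_m[ok],
                                records$P_Pa[ok], records$d_A[ok])
  d_W <- records$d_A - d_B
  keep <- ok & !is.na(d_W) & d_W > 0
  if (any(!keep)) {
    message(sprintf("rejected %d record(s) with non-positive water spacing",
                    sum(!keep)))
  }
  rec <- records[keep, , drop = FALSE]
  d_B <- d_B[keep]
  d_W <- d_W[keep]
  Delta <- caille_to_delta(rec$eta, rec$d_A)
  # delta-method propagation
  U_dW <- sqrt(rec$U_d_A^2 + rec$U_dB0_A^2)
  dD_dd <- sqrt(rec$eta) / pi
  dD_deta <- ifelse(rec$eta > 0, rec$d_A / (2 * pi * sqrt(rec$eta)), 0)
  U_Delta <- sqrt((dD_dd * rec$U_d_A)^2 + (dD_deta * rec$U_eta)^2)
  U_Delta[U_Delta <= 0] <- 1e-6  # eta = 0 with no eta uncertainty
  stress_dataset(rec$P_Pa, d_W, Delta, U_dW = U_dW, U_Delta = U_Delta,
                 U_P_rel = rec$U_P_rel)
}
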