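## Finite-size extrapolation: observables computed at several mesh
## resolutions N (fixed L) are extrapolated to the continuum limit
## N/L -> infinity, i.e. mesh spacing h = L/N -> 0.

#' Build a resolution series
#'
#' Collects simulations run at identical physical parameters but different
#' mesh resolutions `N` for joint extrapolation.
#'
#' @param entries a list of [run_simulation] results (class
#'   `sim_observables`) at distinct `N`.
#' @return An object of class `resolution_series`.
#' @export
resolution_series <- function(entries) {
  stopifnot(length(entries) >= 1,
            all(vapply(entries, inherits, logical(1), "sim_observables")))
  Ns <- vapply(entries, function(e) e$cfg$N, numeric(1))
  if (anyDuplicated(Ns)) stop("duplicate mesh resolutions in series")
  key <- function(e) c(e$cfg$L, e$cfg$M, e$cfg$K_c, e$cfg$P, e$cfg$T)
  k0 <- key(entries[[1]])
  same <- vapply(entries, function(e) isTRUE(all.equal(key(e), k0)), logical(1))
  if (!all(same)) stop("entries differ in physical parameters, not only in N")
  structure(list(entries = entries[order(Ns)]), class = "resolution_series")
}

#' Extrapolate observables to the continuum limit
#'
#' Weighted least-squares fit of each observable against the mesh spacing
#' `h = L/N` over the finest `n_use >= 3` resolutions, reporting the
#' intercept at `h = 0` with its propagated uncertainty. The model order is
#' linear in `h` by default (`order = 1`); `order = 2` fits `h^2` instead.
#' With fewer than 3 resolutions no extrapolation is attempted: the
#' finest-N values are returned flagged as unextrapolated.
#'
#' @param series a [resolution_series].
#' @param n_use number of finest resolutions to use (default 3, or all if
#'   more are requested than available).
#' @param order 1 for linear-in-h, 2 for linear-in-h^2.
#' @return A list with `d_W`, `se_dW`, `delta2`, `se_delta2`,
#'   `extrapolated` (logical), per-observable fit diagnostics
#'   (`residuals`, `chi2`), and the `h` values used.
#' @export
extrapolate_observables <- function(series, n_use = 3, order = 1) {
  stopifnot(inherits(series, "resolution_series"), order %in% c(1, 2))
  ent <- series$entries
  n <- length(ent)
  if (n < 3) {
    fin <- ent[[n]]
    warning("fewer than 3 resolutions: returning finest-N values unextrapolated")
    return(list(d_W = fin$d_W, se_dW = fin$se_dW,
                delta2 = fin$delta2, se_delta2 = fin$se_delta2,
                extrapolated = FALSE, h = fin$cfg$L / fin$cfg$N))
  }
  n_use <- min(max(n_use, 3), n)
  use <- ent[(n - n_use + 1):n]  # finest (largest N) resolutions
  h <- vapply(use, function(e) e$cfg$L / e$cfg$N, numeric(1))
  x <- if (order == 1) h else h^2

  fit1 <- function(y, se) {
    w <- 1 / pmax(se, 1e-12)^2
    X <- cbind(1, x)
    XtWX <- crossprod(X, w * X)
    beta <- solve(XtWX, crossprod(X, w * y))
    r <- y - as.numeric(X %*% beta)
    # intercept SE propagated from the stated measurement uncertainties
    cov_b <- solve(XtWX)
    list(value = beta[1], se = sqrt(cov_b[1, 1]), slope = beta[2],
         residuals = r, chi2 = sum(w * r^2))
  }
  f_dW <- fit1(vapply(use, `[[`, numeric(1), "d_W"),
               vapply(use, `[[`, numeric(1), "se_dW"))
  f_d2 <- fit1(vapply(use, `[[`, numeric(1), "delta2"),
               vapply(use, `[[`, numeric(1), "se_delta2"))

  hull_flag <- function(f, vals, ses) {
    lo <- min(vals - 3 * ses)
    hi <- max(vals + 3 * ses)
    f$value < lo || f$value > hi
  }
  vals_dW <- vapply(use, `[[`, numeric(1), "d_W")
  ses_dW <- vapply(use, `[[`, numeric(1), "se_dW")
  vals_d2 <- vapply(use, `[[`, numeric(1), "delta2")
  ses_d2 <- vapply(use, `[[`, numeric(1), "se_delta2")

  list(d_W = f_dW$value, se_dW = f_dW$se,
       delta2 = f_d2$value, se_delta2 = f_d2$se,
       extrapolated = TRUE, order = order, h = h,
       diagnostics = list(d_W = f_dW, delta2 = f_d2),
       outside_hull = c(d_W = hull_flag(f_dW, vals_dW, ses_dW),
                        delta2 = hull_flag(f_d2, vals_d2, ses_d2)))
}
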