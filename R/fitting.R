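## Least-squares fitting of the interaction parameters (A, lambda, K_c) to
## an osmotic-stress dataset of (P, d_W, Delta) triples. The model values
## are stack-simulation observables; the Jacobian comes from histogram
## reweighting of the archived samples, and steps are taken by a damped
## (Levenberg-Marquardt / trust-region) Gauss-Newton iteration with
## reflective positivity bounds, re-simulating at each accepted step.

#' Construct an osmotic-stress dataset
#'
#' @param P osmotic pressures (Pa), non-negative.
#' @param d_W water spacings (A), positive.
#' @param Delta fluctuation amplitudes (A), non-negative.
#' @param U_dW,U_Delta experimental 1-sigma uncertainties (A), positive.
#' @param U_P_rel relative pressure uncertainty; default 0.06 (pipetting
#'   error of viscous polymer solutions).
#' @return A `data.frame` of class `stress_dataset` with columns `P_Pa`,
#'   `dW_A`, `U_dW_A`, `Delta_A`, `U_Delta_A`, `U_P_rel`.
#' @export
stress_dataset <- function(P, d_W, Delta, U_dW, U_Delta, U_P_rel = 0.06) {
  n <- length(P)
  stopifnot(length(d_W) == n, length(Delta) == n)
  U_dW <- rep_len(U_dW, n)
  U_Delta <- rep_len(U_Delta, n)
  U_P_rel <- rep_len(U_P_rel, n)
  if (any(P < 0)) stop("pressures must be non-negative")
  if (any(d_W <= 0)) stop("water spacings must be positive")
  if (any(Delta < 0)) stop("fluctuation amplitudes must be non-negative")
  if (any(U_dW <= 0) || any(U_Delta <= 0)) stop("uncertainties must be positive")
  structure(data.frame(P_Pa = P, dW_A = d_W, U_dW_A = U_dW,
                       Delta_A = Delta, U_Delta_A = U_Delta,
                       U_P_rel = U_P_rel),
            class = c("stress_dataset", "data.frame"))
}

#' Read / write the dataset CSV interchange format
#'
#' Columns: `P_Pa`, `dW_A`, `U_dW_A`, `Delta_A`, `U_Delta_A`, `U_P_rel`.
#'
#' @param path file path.
#' @return [read_stress_dataset] returns a `stress_dataset`.
#' @export
read_stress_dataset <- function(path) {
  df <- utils::read.csv(path)
  need <- c("P_Pa", "dW_A", "U_dW_A", "Delta_A", "U_Delta_A", "U_P_rel")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  stress_dataset(df$P_Pa, df$dW_A, df$Delta_A, U_dW = df$U_dW_A,
                 U_Delta = df$U_Delta_A, U_P_rel = df$U_P_rel)
}

#' @rdname read_stress_dataset
#' @param dataset a `stress_dataset`.
#' @export
write_stress_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Effective uncertainty of an observable
#'
#' Combines the experimental uncertainty, the simulation (Monte Carlo)
#' uncertainty, and the pressure uncertainty propagated through the slope of
#' the observable with pressure:
#' \deqn{U_{eff}^2 = U(f_{exp})^2 + U(f_{sim})^2 +
#'       (\partial f_{sim}/\partial P \cdot U(P))^2.}
#'
#' @param U_exp experimental uncertainty.
#' @param U_sim simulation uncertainty.
#' @param dfdP derivative of the simulated observable with pressure.
#' @param U_P absolute pressure uncertainty.
#' @return Effective 1-sigma uncertainty (same units as the observable).
#' @export
effective_uncertainty <- function(U_exp, U_sim = 0, dfdP = 0, U_P = 0) {
  u2 <- U_exp^2 + U_sim^2 + (dfdP * U_P)^2
  if (any(u2 <= 0)) stop("zero effective uncertainty would give infinite weight")
  sqrt(u2)
}

## Derivative of f with respect to P on a (sorted, distinct) pressure grid
## by non-uniform finite differences; one-sided at the edges.
grid_derivative <- function(P, f) {
  n <- length(P)
  if (n == 1) return(0)
  d <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) {
      d[i] <- (f[2] - f[1]) / (P[2] - P[1])
    } else if (i == n) {
      d[i] <- (f[n] - f[n - 1]) / (P[n] - P[n - 1])
    } else {
      h1 <- P[i] - P[i - 1]
      h2 <- P[i + 1] - P[i]
      d[i] <- (h1^2 * f[i + 1] - h2^2 * f[i - 1] + (h2^2 - h1^2) * f[i]) /
        (h1 * h2 * (h1 + h2))
    }
  }
  d
}

#' Chi-squared of a simulated model against a dataset
#'
#' \deqn{\chi^2 = \sum_i \left(\frac{d_{W,i} - d_W(P_i)}{U_{eff}(d_{W,i})}\right)^2
#'   + \left(\frac{\Delta_i - \Delta(P_i)}{U_{eff}(\Delta_i)}\right)^2}
#' with effective uncertainties per [effective_uncertainty]. The simulated
#' table must provide a row for every dataset pressure.
#'
#' @param dataset a [stress_dataset].
#' @param sim a `data.frame` with columns `P`, `d_W`, `Delta`, `U_sim_dW`,
#'   `U_sim_Delta`, and optionally `ddW_dP`, `dDelta_dP` (defaults 0).
#' @return A list with `chi2`, `chi2_red`, `n_free` (\eqn{\tilde N} = 2 x
#'   points - 3), the stacked `residuals` (d_W block then Delta block) and
#'   the effective uncertainties.
#' @export
chi_squared <- function(dataset, sim) {
  stopifnot(inherits(dataset, "stress_dataset"))
  idx <- match(dataset$P_Pa, sim$P)
  if (anyNA(idx)) {
    stop("no simulation at pressures: ",
         paste(unique(dataset$P_Pa[is.na(idx)]), collapse = ", "))
  }
  sim <- sim[idx, , drop = FALSE]
  if (is.null(sim$ddW_dP)) sim$ddW_dP <- 0
  if (is.null(sim$dDelta_dP)) sim$dDelta_dP <- 0
  U_P <- dataset$U_P_rel * dataset$P_Pa
  u_dW <- effective_uncertainty(dataset$U_dW_A, sim$U_sim_dW, sim$ddW_dP, U_P)
  u_D <- effective_uncertainty(dataset$U_Delta_A, sim$U_sim_Delta,
                               sim$dDelta_dP, U_P)
  r <- c((dataset$dW_A - sim$d_W) / u_dW,
         (dataset$Delta_A - sim$Delta) / u_D)
  chi2 <- sum(r^2)
  n_free <- 2L * nrow(dataset) - 3L
  list(chi2 = chi2, chi2_red = chi2 / n_free, n_free = n_free,
       residuals = r, U_eff_dW = u_dW, U_eff_Delta = u_D)
}

## Simulate the stack at each dataset pressure for parameters
## lambda = list(logA, lam, K_c); returns sims (list) and the model table.
simulate_isotherm <- function(pressures, lambda, template, sim_opts, seed) {
  A <- 10^lambda$logA
  ip <- interaction_params(A = A, lam = lambda$lam, H = template$H,
                           A_st = template$A_st, lam_st = template$lam_st,
                           a_cut = template$a_cut, steric = template$steric)
  ord <- order(pressures)
  # seed by pressure rank, not row position: the fit is then invariant
  # under reordering of the dataset rows
  rk <- rank(pressures, ties.method = "first")
  sims <- vector("list", length(pressures))
  for (i in seq_along(pressures)) {
    cfg <- do.call(sim_config, c(list(K_c = lambda$K_c, P = pressures[i],
                                      seed = seed + rk[i]), sim_opts))
    sims[[i]] <- run_simulation(cfg, ip)
  }
  d_W <- vapply(sims, `[[`, numeric(1), "d_W")
  delta2 <- vapply(sims, `[[`, numeric(1), "delta2")
  se_dW <- vapply(sims, `[[`, numeric(1), "se_dW")
  se_d2 <- vapply(sims, `[[`, numeric(1), "se_delta2")
  Delta <- sqrt(pmax(delta2, 1e-12))
  se_Delta <- se_d2 / (2 * Delta)
  Ps <- pressures[ord]
  tab <- data.frame(P = pressures, d_W = d_W, Delta = Delta,
                    U_sim_dW = se_dW, U_sim_Delta = se_Delta)
  tab$ddW_dP <- grid_derivative(Ps, d_W[ord])[order(ord)]
  tab$dDelta_dP <- grid_derivative(Ps, Delta[ord])[order(ord)]
  list(sims = sims, table = tab)
}

## Jacobian of the stacked residual vector with respect to
## (logA, lam, K_c), by histogram reweighting of each pressure's archive.
residual_jacobian <- function(dataset, iso, chi) {
  n <- nrow(dataset)
  idx <- match(dataset$P_Pa, iso$table$P)
  J <- matrix(0, 2 * n, 3,
              dimnames = list(NULL, c("logA", "lam", "K_c")))
  for (i in seq_len(n)) {
    arch <- iso$sims[[idx[i]]]$archive
    Delta_i <- iso$table$Delta[idx[i]]
    for (j in 1:3) {
      par <- c("logA", "lam", "K_c")[j]
      dv <- observable_derivative(arch, par)
      # residual = (data - model)/U_eff: d r/d theta = -(d model/d theta)/U_eff
      J[i, j] <- -dv[["d_dW"]] / chi$U_eff_dW[i]
      J[n + i, j] <- -(dv[["d_delta2"]] / (2 * Delta_i)) / chi$U_eff_Delta[i]
    }
  }
  J
}

#' Fit interaction parameters to an osmotic-stress dataset
#'
#' Iterative least squares on \eqn{\Lambda = (\log_{10} A, \lambda, K_c)}:
#' each iteration simulates the stack at every dataset pressure, builds the
#' weighted residuals with effective uncertainties, obtains the Jacobian by
#' histogram reweighting of the archived samples, and takes a damped
#' Gauss-Newton (Levenberg-Marquardt) step with per-parameter trust-region
#' bounds (at most 15% relative change per iteration, matching the validity
#' of the reweighting) and reflective positivity bounds. A step is accepted
#' only if the freshly simulated chi-squared decreases; common random
#' numbers (fixed per-pressure seeds) keep the stochastic objective
#' comparable across iterations. Parameter uncertainties come from the
#' Gauss-Newton curvature at the optimum, inflated by
#' \eqn{\sqrt{\chi^2_{red}}} when \eqn{\chi^2_{red} > 1}.
#'
#' @param dataset a [stress_dataset] with at least 3 pressure points.
#' @param start named list with `logA`, `lam`, `K_c`, or `NULL` to draw
#'   random starts.
#' @param template an [interaction_params] carrying the fixed constants
#'   (`H`, steric parameters, cutoff); its `A` and `lam` entries are ignored.
#' @param sim_opts named list of [sim_config] arguments shared by all
#'   simulations (e.g. `N`, `M`, `n_equil`, `n_collect`).
#' @param n_starts number of random starts when `start` is `NULL`
#'   (default 3).
#' @param max_iter maximum accepted+rejected iterations per start.
#' @param rel_tol convergence tolerance on the relative step per parameter.
#' @param seed base seed; per-pressure simulation seeds and random starts
#'   derive from it.
#' @param bounds list of `lower`/`upper` named vectors for
#'   (`logA`, `lam`, `K_c`).
#' @param verbose print per-iteration progress.
#' @return An object of class `fit_result`: `params` (list `logA`, `lam`,
#'   `K_c`), `param_errors`, `chi2`, `chi2_red`, `n_free`, `n_iter`,
#'   `converged`, `start_point`, `trace` and the final model `table`.
#' @export
fit_interaction_params <- function(dataset, start = NULL, template,
                                   sim_opts = list(), n_starts = 3,
                                   max_iter = 10, rel_tol = 1e-2,
                                   seed = 1L,
                                   bounds = list(
                                     lower = c(logA = 6.5, lam = 0.5, K_c = 5),
                                     upper = c(logA = 10, lam = 3.5, K_c = 400)),
                                   verbose = FALSE) {
  stopifnot(inherits(dataset, "stress_dataset"))
  if (nrow(dataset) < 3) stop("need at least 3 pressure points")
  stopifnot(inherits(template, "interaction_params"))

  if (!is.null(start)) {
    starts <- list(start)
  } else {
    set.seed(seed)
    starts <- replicate(n_starts, list(
      logA = stats::runif(1, 7.6, 9.0),
      lam = stats::runif(1, 1.0, 2.2),
      K_c = stats::runif(1, 25, 160)), simplify = FALSE)
  }

  best <- NULL
  for (si in seq_along(starts)) {
    res <- fit_single_start(dataset, starts[[si]], template, sim_opts,
                            max_iter, rel_tol,
                            seed = seed + 1000L * si, bounds = bounds,
                            verbose = verbose)
    if (is.null(best) || res$chi2 < best$chi2) best <- res
  }
  best
}

fit_single_start <- function(dataset, start, template, sim_opts,
                             max_iter, rel_tol, seed, bounds,
                             verbose = FALSE) {
  lam_cur <- start
  reflect <- function(l) {
    v <- c(logA = l$logA, lam = l$lam, K_c = l$K_c)
    for (k in names(v)) {
      if (v[k] < bounds$lower[k]) v[k] <- 2 * bounds$lower[k] - v[k]
      if (v[k] > bounds$upper[k]) v[k] <- 2 * bounds$upper[k] - v[k]
      v[k] <- min(max(v[k], bounds$lower[k]), bounds$upper[k])
    }
    list(logA = unname(v["logA"]), lam = unname(v["lam"]),
         K_c = unname(v["K_c"]))
  }
  lam_cur <- reflect(lam_cur)

  evaluate <- function(l) {
    iso <- simulate_isotherm(dataset$P_Pa, l, template, sim_opts, seed)
    chi <- chi_squared(dataset, iso$table)
    list(iso = iso, chi = chi)
  }
  ev <- evaluate(lam_cur)
  mu <- 1e-2
  trace <- list()
  converged <- FALSE
  n_iter <- 0
  J <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    J <- residual_jacobian(dataset, ev$iso, ev$chi)
    r <- ev$chi$residuals
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (try in 1:4) {
      Hm <- JtJ + mu * diag(diag(JtJ) + 1e-12, 3)
      delta <- tryCatch(-solve(Hm, g), error = function(e) NULL)
      if (is.null(delta)) { mu <- mu * 10; next }
      delta <- as.numeric(delta)
      names(delta) <- colnames(J)
      # trust region: at most 15% relative move per parameter
      cap <- c(logA = 0.15, lam = 0.15 * lam_cur$lam, K_c = 0.15 * lam_cur$K_c)
      delta <- pmin(pmax(delta, -cap), cap)
      cand <- reflect(list(logA = lam_cur$logA + delta[["logA"]],
                           lam = lam_cur$lam + delta[["lam"]],
                           K_c = lam_cur$K_c + delta[["K_c"]]))
      ev_new <- evaluate(cand)
      if (ev_new$chi$chi2 < ev$chi$chi2) {
        rel_step <- max(abs(delta[["logA"]]) / max(abs(lam_cur$logA), 1),
                        abs(delta[["lam"]]) / lam_cur$lam,
                        abs(delta[["K_c"]]) / lam_cur$K_c)
        lam_cur <- cand
        ev <- ev_new
        mu <- max(mu / 3, 1e-5)
        step_ok <- TRUE
        if (verbose) {
          message(sprintf(
            "iter %d: chi2 = %.3f, logA = %.3f, lam = %.3f, K_c = %.1f",
            it, ev$chi$chi2, lam_cur$logA, lam_cur$lam, lam_cur$K_c))
        }
        if (rel_step < rel_tol) converged <- TRUE
        break
      } else {
        mu <- mu * 4
      }
    }
    trace[[it]] <- c(chi2 = ev$chi$chi2, logA = lam_cur$logA,
                     lam = lam_cur$lam, K_c = lam_cur$K_c, accepted = step_ok)
    if (converged) break
    if (!step_ok && it > 1) { converged <- TRUE; break }  # gradient-noise stop
  }

  chi2_red <- ev$chi$chi2_red
  cov <- tryCatch(solve(crossprod(J)), error = function(e) matrix(NA, 3, 3))
  perr <- sqrt(pmax(diag(cov), 0)) * sqrt(max(chi2_red, 1))
  names(perr) <- c("logA", "lam", "K_c")

  structure(list(params = lam_cur, param_errors = perr,
                 chi2 = ev$chi$chi2, chi2_red = chi2_red,
                 n_free = ev$chi$n_free, n_iter = n_iter,
                 converged = converged, start_point = start,
                 trace = do.call(rbind, trace), table = ev$iso$table),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Osmotic-stress fit result:\n")
  cat(sprintf("  log10(A/Pa) = %.3f +/- %.3f\n", x$params$logA,
              x$param_errors[["logA"]]))
  cat(sprintf("  lambda      = %.3f +/- %.3f A\n", x$params$lam,
              x$param_errors[["lam"]]))
  cat(sprintf("  K_c         = %.1f +/- %.1f zJ\n", x$params$K_c,
              x$param_errors[["K_c"]]))
  cat(sprintf("  chi2_red = %.3f (chi2 = %.3f, Ntilde = %d), %d iterations%s\n",
              x$chi2_red, x$chi2, x$n_free, x$n_iter,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
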