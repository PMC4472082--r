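#!/usr/bin/env Rscript

## Stage 3: optimizer self-consistency. Generates a synthetic dataset with
## the stack simulator at known parameters (the liquid-disordered set:
## log10 A = 8.3, lambda = 1.37 A, K_c = 44 zJ), then fits starting from a
## deliberately displaced parameter set and checks that the optimizer
## returns to the truth. Reduced MC settings (N = 8, M = 8, 1.5e3/5e3 MCS).
## Takes ~10-15 min on one CPU. Output: results/fit_selfconsistency.json.

library(lamstack)

seed <- 20260925L
dir.create("results", showWarnings = FALSE)

truth <- list(logA = 8.3, lam = 1.37, K_c = 44)
tmpl <- interaction_params(A = 10^truth$logA, lam = truth$lam, H = 4.08)
opts <- list(N = 8, M = 8, n_equil = 1500, n_collect = 5000)
pressures <- c(2e4, 1e5, 4e5, 1.5e6, 6e6)

spec <- synthetic_spec(logA = truth$logA, lam = truth$lam, K_c = truth$K_c,
                       H = 4.08, pressures = pressures,
                       U_P_rel = 1e-6, U_dW = 0.15, U_Delta_rel = 0.02,
                       generator = "simulator", sim_opts = opts, seed = seed)
gen <- generate_synthetic(spec)
cat("synthetic dataset:\n")
print(gen$dataset)

start <- list(logA = 8.0, lam = 1.7, K_c = 70)
cat(sprintf("start: logA = %.2f, lam = %.2f, K_c = %.0f\n",
            start$logA, start$lam, start$K_c))

fit <- fit_interaction_params(gen$dataset, start = start, template = tmpl,
                              sim_opts = opts, max_iter = 8,
                              seed = seed + 1, verbose = TRUE)
print(fit)

jsonlite::write_json(
  list(truth = truth, start = start,
       fitted = fit$params, errors = as.list(fit$param_errors),
       chi2_red = fit$chi2_red, n_iter = fit$n_iter,
       converged = fit$converged),
  "results/fit_selfconsistency.json", auto_unbox = TRUE, digits = NA)
write_manifest("results/fit_selfconsistency_manifest.json",
               command = "fit-selfconsistency",
               config = c(opts, list(pressures = pressures)),
               seed = seed, outputs = "results/fit_selfconsistency.json")
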