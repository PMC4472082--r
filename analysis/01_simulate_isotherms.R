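#!/usr/bin/env Rscript

## Stage 1: simulate osmotic pressure-distance isotherms for the two
## coexisting phases at their fitted interaction parameters.
##
## Settings: N = 16 mesh (h = 44 A; the undulation fit window d_W >= 14 A
## must be resolved, which rules out N <= 8), M = 8 membranes, L = 700 A,
## 1000/3500 MCS. Takes ~20 min on one CPU. Output:
## results/isotherm_ld.csv, results/isotherm_lo.csv.

library(lamstack)

seed <- 20260923L
dir.create("results", showWarnings = FALSE)

phases <- list(
  ld = list(p = interaction_params(A = 10^8.3, lam = 1.37, H = 4.08),
            K_c = 44),
  lo = list(p = interaction_params(A = 10^8.1, lam = 1.74, H = 4.15),
            K_c = 120))

pressures <- c(0, 2e3, 5e3, 1e4, 1.8e4, 3e4, 2e5, 1e6)

for (ph in names(phases)) {
  cat(sprintf("== %s phase ==\n", ph))
  rows <- lapply(seq_along(pressures), function(i) {
    cfg <- sim_config(K_c = phases[[ph]]$K_c, P = pressures[i], N = 16,
                      M = 8, n_equil = 1000, n_collect = 3500,
                      seed = seed + i)
    o <- run_simulation(cfg, phases[[ph]]$p)
    cat(sprintf("  P = %8.0f Pa: d_W = %6.3f +/- %5.3f A, Delta = %5.3f A\n",
                pressures[i], o$d_W, o$se_dW, sqrt(o$delta2)))
    data.frame(P_Pa = pressures[i], dW_A = o$d_W, se_dW_A = o$se_dW,
               Delta_A = sqrt(o$delta2),
               se_Delta_A = o$se_delta2 / (2 * sqrt(o$delta2)),
               tau_MCS = o$tau, acc_mode = o$acc_mode)
  })
  tab <- do.call(rbind, rows)
  out <- sprintf("results/isotherm_%s.csv", ph)
  write.csv(tab, out, row.names = FALSE)
  write_manifest(sprintf("results/isotherm_%s_manifest.json", ph),
                 command = "simulate-isotherm",
                 config = list(phase = ph, K_c = phases[[ph]]$K_c,
                               N = 16, M = 8, L = 700,
                               n_equil = 1000, n_collect = 3500,
                               pressures = pressures),
                 seed = seed, outputs = out)
  cat(sprintf("wrote %s\n", out))
}
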