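#!/usr/bin/env Rscript

## Stage 2: finite-size convergence of the fully hydrated state (P = 0,
## liquid-disordered parameters). Simulates a ladder of mesh resolutions
## at fixed physical parameters and extrapolates d_W and Delta^2 to the
## continuum limit h = L/N -> 0. Takes ~5 min on one CPU.
## Output: results/finite_size.csv, results/finite_size_extrapolation.json.

library(lamstack)

seed <- 20260924L
dir.create("results", showWarnings = FALSE)

ip <- interaction_params(A = 10^8.3, lam = 1.37, H = 4.08)
Ns <- c(6, 8, 12, 16)

sims <- lapply(Ns, function(N) {
  cfg <- sim_config(K_c = 44, P = 0, N = N, M = 8, n_equil = 1500,
                    n_collect = 5000, seed = seed + N)
  o <- run_simulation(cfg, ip)
  cat(sprintf("N = %2d (h = %6.2f A): d_W = %6.3f +/- %5.3f, Delta2 = %6.3f +/- %5.3f\n",
              N, 700 / N, o$d_W, o$se_dW, o$delta2, o$se_delta2))
  o
})

ser <- resolution_series(sims)
ex <- extrapolate_observables(ser, n_use = 3)
ex2 <- extrapolate_observables(ser, n_use = 3, order = 2)
cat(sprintf("continuum limit (linear in h):  d_W = %.2f +/- %.2f A\n",
            ex$d_W, ex$se_dW))
cat(sprintf("continuum limit (h^2 model):    d_W = %.2f +/- %.2f A\n",
            ex2$d_W, ex2$se_dW))
if (abs(ex$d_W - ex2$d_W) > 2 * sqrt(ex$se_dW^2 + ex2$se_dW^2)) {
  cat("NOTE: the two model orders disagree beyond their combined\n",
      "uncertainty: the ladder is not yet in the leading-order regime\n",
      "and finer meshes (N = 24, 32) are needed for a converged limit.\n")
}

tab <- data.frame(N = Ns, h_A = 700 / Ns,
                  dW_A = sapply(sims, `[[`, "d_W"),
                  se_dW_A = sapply(sims, `[[`, "se_dW"),
                  delta2_A2 = sapply(sims, `[[`, "delta2"),
                  se_delta2_A2 = sapply(sims, `[[`, "se_delta2"))
write.csv(tab, "results/finite_size.csv", row.names = FALSE)
jsonlite::write_json(
  list(d_W = ex$d_W, se_dW = ex$se_dW, delta2 = ex$delta2,
       se_delta2 = ex$se_delta2, order = ex$order, h_used = ex$h),
  "results/finite_size_extrapolation.json", auto_unbox = TRUE, digits = NA)
write_manifest("results/finite_size_manifest.json",
               command = "finite-size",
               config = list(K_c = 44, P = 0, M = 8, L = 700, Ns = Ns),
               seed = seed,
               outputs = c("results/finite_size.csv",
                           "results/finite_size_extrapolation.json"))
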