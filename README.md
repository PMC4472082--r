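# lamstack

Monte Carlo analysis of the forces that hold multilamellar membrane
stacks together.

## What this solves

In osmotic-stress experiments on lipid multibilayers (including the
aligned liquid-ordered/liquid-disordered domains of raft-mimicking
mixtures), a known osmotic pressure `P` compresses the stack while
small-angle x-ray scattering measures the lamellar repeat distance `d`
and the Caillé fluctuation parameter `η`, i.e. the water spacing
`d_W = d − d_B` and the bending-fluctuation amplitude `Δ = d·√η/π`.
Extracting the underlying interactions from such isotherms is hard
because the entropic undulation repulsion is *not* additive with the bare
forces. `lamstack` avoids mean-field/additivity assumptions by simulating
the stack explicitly and fitting the simulation to the data.

The stack of `M` membranes with displacements `u_m(x, y)` (periodic in
all directions) carries the Hamiltonian

    H = Σ_m ∫ [ (K_c/2) (∇² u_m)² + Φ(a_m) ] dx dy,
    a_m = u_{m+1} − u_m + ā  ≥ 0,

with the bare potential per unit area

    Φ(a) = A λ e^{−a/λ} − H / (12π max(a, a_c)²) + A_st λ_st e^{−a/λ_st}

(hydration repulsion, van der Waals attraction with Hamaker coefficient
`H` clamped below `a_c = 1 Å`, and a sub-angstrom steric term). Sampling
is constant-pressure Metropolis Monte Carlo in Fourier space: each sweep
proposes `N²M` single-mode updates plus one move of the mean spacing `ā`
against the enthalpy `P·M·L²·ā`. Observables are `d_W = ⟨ā⟩` and
`Δ² = ⟨ mean_(m,x,y) (a_m − d_W)² ⟩`, extrapolated to the continuum mesh
limit from a ladder of resolutions `N`. A trust-region least-squares
driver fits `Λ = (log₁₀A, λ, K_c)` to a measured `(P, d_W, Δ)` dataset,
with the Jacobian obtained by histogram reweighting of archived samples
and effective uncertainties

    U_eff²(f) = U²(f_exp) + U²(f_sim) + (∂f_sim/∂P · U(P))².

Fitted pressures decompose as `P_und = P − P_hyd − P_vdW − P_st`, with the
effective undulation decay length from an exponential fit at
`d_W ≥ 14 Å`, and the stiff-ring check `δ′² = 12 K_c / K_A`.

## Worked example

Simulate a liquid-disordered-like stack at full hydration and inspect the
observables:

```r
library(lamstack)

ld <- interaction_params(A = 10^8.3, lam = 1.37, H = 4.08)
cfg <- sim_config(K_c = 44, P = 0, N = 12, M = 8,
                  n_equil = 1500, n_collect = 5000, seed = 50)
obs <- run_simulation(cfg, ld)
obs
#> Membrane-stack MC observables:
#>   d_W    = 16.663 +/- 0.129 A
#>   Delta2 = 44.345 +/- 1.108 A^2  (Delta = 6.659 A)
#>   acceptance: modes 0.50, abar 0.55; tau = 195 MCS
```

At zero osmotic pressure the hydration, van der Waals and undulation
pressures balance at a water spacing close to 17 Å with ~6.6 Å
fluctuations — the fully hydrated state of a disordered phase. The same
parameters at a coarser mesh give a smaller spacing (13.7 Å at `N = 8`,
11.2 Å at `N = 6`): the undulation repulsion needs mesh resolution, which
is why production runs extrapolate a resolution ladder with
`extrapolate_observables()`.

The stiff-ring consistency check for the two phases (bending rigidities
44 and 120 zJ, area-extension moduli 430 and 2100 mN/m):

```r
round(ring_size(K_c = 44, K_A = 430))    # 11 (A)  - Ld
round(ring_size(K_c = 120, K_A = 2100))  #  8 (A)  - Lo
```

both close to the ~9 Å cholesterol ring size.

The numbered scripts under `analysis/` run the full chain — isotherm
sweeps for both phases, finite-size extrapolation, optimizer
self-consistency (fit of simulator-generated data from a displaced start)
and the pressure decomposition — writing tables and JSON summaries under
`results/`.

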