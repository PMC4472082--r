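---
title: "Monte Carlo analysis of forces in multilamellar membrane stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo analysis of forces in multilamellar membrane stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lamstack)
```

## The physical problem

Stacks of lipid membranes (multilamellar vesicles, aligned multibilayers,
and in particular the aligned liquid-ordered/liquid-disordered domains of
raft-mimicking mixtures) are held together by a balance of forces acting
across the water layers: a short-ranged, exponentially decaying hydration
repulsion; a van der Waals attraction; a very short-ranged steric
repulsion; and the entropic repulsion generated by thermally excited
bending undulations of the membranes themselves. Osmotic-stress
experiments probe this balance: a known osmotic pressure $P$ is applied
(e.g. with PEG solutions) and small-angle x-ray scattering measures the
lamellar repeat distance $d$, the Caillé fluctuation parameter $\eta$, and
hence the water spacing $d_W = d - d_B$ and the fluctuation amplitude
$\Delta = d\sqrt{\eta}/\pi$.

The undulation repulsion is *not* additive with the bare forces: the bare
potentials modify the fluctuation spectrum, which feeds back on the
effective interaction. Mean-field/additivity treatments of this coupling
are uncontrolled. This package therefore takes the simulation route: the
stack is simulated explicitly, with the bare potentials and the bending
elasticity as microscopic input, and the interaction parameters are
obtained by fitting simulated observables to the measured
pressure–distance and pressure–fluctuation isotherms.

## Model and ensemble

The stack consists of $M$ membranes with displacement fields $u_m(x,y)$ on
an $L \times L$ patch, periodic in $x$, $y$ and $m$. The Hamiltonian is

$$H = \sum_{m=0}^{M-1} \int \left[ \frac{K_c}{2}\left(\nabla^2 u_m\right)^2
 + \Phi(a_m) \right] dx\,dy,
 \qquad a_m = u_{m+1} - u_m + \bar a \ge 0,$$

with bending rigidity $K_c$ and the bare potential per unit area

$$\Phi(a) = A\lambda e^{-a/\lambda} - \frac{H}{12\pi \max(a, a_c)^2}
 + A_{st}\lambda_{st} e^{-a/\lambda_{st}}.$$

Defaults: steric constants $A_{st} = 3.6$ GPa, $\lambda_{st} = 0.6$ Å
(unimportant at realistic parameters but included); van der Waals cutoff
$a_c = 1$ Å. The cutoff *clamps* the $1/a^2$ term below $a_c$ (constant
potential, zero force) rather than dropping it: this keeps the energy
finite and continuous at $a_c$ so the Metropolis acceptance is always
well defined. Non-interpenetration ($a_m \ge 0$) is enforced by rejection.

The ensemble is constant osmotic pressure: the mean spacing $\bar a$ is a
degree of freedom and the enthalpy term $P M L^2 \bar a$ enters the
Metropolis weight. Because $\bar a$ is a single additive coordinate the
volume-entropy Jacobian is unity. The observables are
$d_W = \langle \bar a\rangle$ and
$\Delta^2 = \langle\, \overline{(a_m(x,y) - d_W)^2} \,\rangle$, the spatial
average running over $(m, x, y)$ and the angled brackets over Monte Carlo
time. $\Delta^2$ depends only on the local separations, so it is invariant
under a uniform shift of all membranes (the gauge direction that the
per-sweep recentering removes).

Internal units are Å for lengths, zJ for energies and Pa for pressures;
the single conversion constant (1 Pa·Å$^3$ = $10^{-9}$ zJ) and $k_B$ live
in `lamstack_constants`.

## Monte Carlo moves and step adaptation

Each membrane is discretized on an $N \times N$ mesh (spacing $h = L/N$).
Updates are proposed in the Fourier coefficients $u_m(q)$: one Monte Carlo
step (MCS) comprises $N^2 M$ single-mode proposals (random membrane,
random independent mode) plus one uniform-step proposal on $\bar a$. A
mode proposal perturbs (Re, Im) of one independent coefficient jointly
with Gaussian increments (self-conjugate modes, those with $2q \equiv 0$,
are real and get a single real increment); Hermitian symmetry is preserved
exactly. The independent modes are enumerated once as the lexicographically
smaller member of each conjugate pair.

The bending energy is evaluated spectrally as
$\frac{K_c}{2} L^2 \sum_q |\hat q|^4 |u_m(q)|^2$ with the
*discrete-Laplacian* eigenvalues
$\hat q^2 = (4/h^2)[\sin^2(\pi j/N) + \sin^2(\pi k/N)]$, so the spectral
form agrees exactly (by Parseval) with the real-space five-point Laplacian
that the interaction sum lives on; the test suite checks this equivalence
on random states. The interaction energy is the site sum
$h^2 \sum_{m,x,y} \Phi(a_m)$.

Proposal widths are adapted only during equilibration and frozen during
collection (so detailed balance holds for every recorded sample). Two
schemes are available, per mode shell (modes grouped by $|\hat q|^4$):

* **ARM** (acceptance ratio method, default): every 50 MCS each shell step
  is multiplied by (measured acceptance / target), clipped to $[1/2, 2]$;
  target acceptance 0.5.
* **DOMC** (dynamically optimized): shell steps are tied to the running
  RMS mode amplitude of the shell, with one global prefactor steered by
  the same acceptance rule. The originally published optimization schedule
  is not reproduced verbatim (its reference implementation is not
  available); this variant keeps its defining idea — steps proportional to
  the local mode scale — and ARM remains the default.

Initial steps come from the harmonic (equipartition) estimate
$\sigma_q^2 = k_B T / [L^2(K_c \hat q^4 + \Phi''_{rep}(\bar a_0))]$.

Incrementally tracked energies (interaction sum, spectral bending sum) are
recomputed from scratch every 100 MCS; the maximal relative drift is
reported with the observables (typically $10^{-13}$) and the totals are
resynchronized.

## Error bars and convergence

The integrated autocorrelation time $\tau$ of the $\bar a$ series is
estimated with a Sokal-windowed sum; standard errors of $d_W$ and
$\Delta^2$ come from blocking with block length $\ge 10\tau$. A run is
flagged as under-converged when $\tau$ exceeds a tenth of the collection
length (the design target is a collection length of $\sim 100\tau$,
which the default 10$^4$ MCS satisfies for the standard systems).

Observables depend significantly on the mesh resolution: the mesh must
resolve the collision wavelength $\ell \sim \sqrt{K_c/k_BT}\, d_W$ for the
undulation repulsion to be fully developed. Production protocol is
therefore a ladder of resolutions ($N \in \{6, 8, 12, 16, 24, 32\}$ at
$L = 700$ Å) extrapolated to $h = L/N \to 0$
(`extrapolate_observables()`). The extrapolation model is a weighted
linear fit in $h$ over the finest three resolutions by default; the exact
convergence law is not known analytically, so the model order is
configurable (`order = 2` for $h^2$) and residual diagnostics plus a
convex-hull flag are reported. With fewer than three resolutions the
function refuses and returns the finest-$N$ values, flagged.

## Histogram reweighting and the fit

Each archived sample stores $\bar a$, the spatial mean of $a^2$, the
spectral bending sum, and a histogram of local separations (bin width
0.1 Å up to 80 Å — fine enough to resolve a $\lambda \approx 1.4$ Å decay
with sub-percent quadrature error, small enough to keep archives
compact). The energy at perturbed parameters
$\Lambda' = (A', \lambda', K_c')$ is then computable per sample — bending
from the stored sum, hydration (and steric) by quadrature over the
histogram, van der Waals/wall/enthalpy unchanged — giving weights
$w_s \propto e^{-[E(\Lambda';s) - E(\Lambda;s)]/k_BT}$
(`reweight_observable()`). Both energies are evaluated from the same
histogram so the binning error cancels to first order. The effective
sample size must stay above 20% of the archive; otherwise the
perturbation has left the trust region and the caller must re-simulate.
Parameter derivatives (`observable_derivative()`) are central finite
differences of reweighted observables at ±1% — chosen over an analytic
weighted-covariance estimator for robustness to Monte Carlo noise.

`fit_interaction_params()` minimizes

$$\chi^2(\Lambda) = \sum_i
 \left[\frac{d_{W,i} - d_W(P_i;\Lambda)}{U_{eff}(d_{W,i})}\right]^2 +
 \left[\frac{\Delta_i - \Delta(P_i;\Lambda)}{U_{eff}(\Delta_i)}\right]^2,
 \qquad
 U_{eff}^2(f) = U^2(f_{exp}) + U^2(f_{sim}) +
 \left(\frac{\partial f_{sim}}{\partial P} U(P_i)\right)^2,$$

over $\Lambda = (\log_{10} A, \lambda, K_c)$. The amplitude is
parameterized on the log scale (it is determined to order-of-magnitude
precision; this also conditions the Jacobian), $\lambda$ and $K_c$ carry
reflective positivity bounds. $\partial f_{sim}/\partial P$ comes from
finite differences across the simulated pressure grid. Steps are damped
Gauss–Newton (Levenberg–Marquardt) with a per-parameter trust region of
15% per iteration — matching the reweighting validity — and are accepted
only if a fresh simulation at the candidate lowers $\chi^2$. Common random
numbers (per-pressure seeds fixed by pressure *rank*, making the fit
invariant under dataset row order) keep the stochastic objective
comparable across iterations. Iteration stops at a relative step below
$10^{-2}$, or when no improving step is found (the gradient-noise stop:
near the optimum the true gradient vanishes and the stochastic gradient
is noise-dominated). The multi-start driver (default 3 random starts)
guards against local minima. Parameter errors are
$\sqrt{\mathrm{diag}[(J^TJ)^{-1}]}$ inflated by $\sqrt{\chi^2_{red}}$ when
$\chi^2_{red} > 1$; $\chi^2_{red} = \chi^2/\tilde N$ with
$\tilde N = 2 n_{points} - 3$.

How $U(f_{sim})$ is combined for extrapolated observables is not uniquely
prescribed; the package propagates the intercept uncertainty of the
finite-size fit, which reduces to the Monte Carlo error when no
extrapolation is performed.

## Pressure decomposition

With fitted parameters in hand, the total pressure dissects as
$P_{und} = P - P_{hyd} - P_{vdW} - P_{st}$ with
$P_{hyd} = A e^{-d_W/\lambda}$ and $P_{vdW} = -H/(6\pi d_W^3)$
(`decompose_pressure()`); the identity
$P_{hyd} + P_{vdW} + P_{st} + P_{und} = P$ holds pointwise at machine
precision by construction. The effective undulation decay length comes
from an *unweighted* log-linear fit of $P_{und}(d_W)$ restricted to
$d_W \ge 14$ Å: the undulation pressure is not a perfect exponential, and
restricting to large separations is the established convention; the
weighting scheme is not prescribed, so the simplest choice is used and
the fit window is a parameter. Points with $P_{und} \le 0$ are excluded
with a warning; a decomposition with no undulation excess refuses the fit.
The hydration/undulation crossing $d_\times$ (where $P_{hyd} = P_{und}$)
is located by monotone cubic interpolation of their difference.
`ring_size()` implements the stiff-ring consistency check
$\delta'^2 = 12 K_c / K_A$ linking bending and stretching moduli through
the cholesterol ring size.

## Synthetic data

`generate_synthetic()` emulates the experimental design so every
downstream stage is testable without the (undeposited) measured
isotherms: 8–12 pressures from 0 to ~10 MPa, water spacings ~5–17 Å,
fluctuation amplitudes ~2–7 Å, relative pressure uncertainty 6%
(pipetting of viscous PEG solutions). The experimental magnitudes of
$U(d_W)$ and $U(\Delta)$ are not tabulated anywhere usable, so the
defaults — $U(d_W) = 0.5$ Å absolute, $U(\Delta) = 5\%$ relative — are
stated assumptions of this package, chosen to sit between the SAXS fit
uncertainty (±2%) and typical published error bars; both are
configurable. The reference generator is the simulator itself (the
dataset then contains exactly the physics the fit assumes); a mean-field
soft-confinement surrogate (`meanfield_spacing()`, exponential undulation
pressure with decay $2\lambda$ and amplitude
$\frac{k_BT}{16\lambda}\sqrt{A/(\lambda K_c)}$) is provided *only* for
initialization and quick checks — mean-field additivity is precisely the
approximation the simulation route exists to avoid, and the surrogate
visibly underestimates the undulation repulsion (its zero-pressure
spacing is ~13.5 Å against ~17 Å from the simulation at converged
meshes). What passing synthetic-recovery tests demonstrate is that the
estimator is consistent with its own forward model at matched settings;
they do not probe SAXS line-shape systematics, which in real data can
inflate $\chi^2_{red}$ for highly ordered phases.

## Problem sizes used in tests and analyses

The packaged analyses and tests run at reduced, desk-scale settings chosen
once: unit tests use $N = 6$, $M = 4$, $\sim$600/2500 MCS; the optimizer
self-consistency check uses $N = 8$, $M = 8$, 1200/4000 MCS with 4
pressures; isotherm sweeps and the full-hydration check use $N = 16$
(without extrapolation) because $h = L/N$ must resolve the undulation fit
window $d_W \ge 14$ Å — at $N = 8$ the fully hydrated liquid-disordered
stack only reaches $d_W \approx 13.7$ Å of mesh-bias origin (measured
ladder: 11.2, 13.7, 16.6, 17.7 Å for $N$ = 6, 8, 12, 16), which would
leave the fit window empty. Even at $N = 16$ the liquid-disordered
undulation decay length retains visible mesh bias (measured
$\lambda_{und}$: 4.05 at $h = 58$ Å, 3.81 at $h = 44$ Å, decreasing
toward $\approx$3.3–3.5 in the $h \to 0$ trend), so fixed-mesh
desk-scale values of $\lambda_{und}$ should be read as upper bounds. The
hard-wall scaling test uses a small stiff box ($L = 180$ Å, $N = 12$,
$M = 2$, $K_c = 10$ zJ) so the collision wavelength is resolved across
its pressure decade; even so, the measured effective exponent at these
resolutions is $\approx -0.36$ rather than exactly $-1/3$ — the
asymptotic Helfrich regime is approached from above as the mesh is
refined. Production-quality parameter values want the full
ladder up to $N = 32$ and $10^4$-MCS collections.

## Known limitations

* The Hamaker coefficient is an input, not a fit parameter; computing it
  from dielectric data is out of scope.
* Single mesh node per membrane degree of freedom: no molecular detail,
  no lateral tension or area exchange, no intra-membrane phase
  separation.
* The finite-size extrapolation law is empirical (linear in $h$ over the
  finest resolutions, optionally $h^2$); results where the two model
  orders disagree by more than their combined uncertainty should be
  re-run at finer meshes.
* Electrostatics are absent (uncharged membranes).
* The PEG concentration-to-pressure equation of state is deliberately not
  hardcoded; pressures are accepted in Pa, or through a user-supplied
  lookup table.
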