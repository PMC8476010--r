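---
title: "Methods: mass-action simulation with stiffness-aware dispatch"
author: "rbmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-action simulation with stiffness-aware dispatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmsim)
```

## The model

A reaction-based model (RBM) is a set of `M` biochemical reactions over
`N` molecular species, encoded by two non-negative integer stoichiometric
matrices `A` (reactant side) and `B` (product side), a vector `K` of
positive kinetic constants and an initial state `X0`. Assuming mass-action
kinetics, reaction `i` fires with flux `k_i * Π_j x_j^(A_ij)` and the full
system is

$$\frac{dX}{dt} = (B - A)^T \left( K \circ X^A \right),$$

a polynomial vector field whose Jacobian is available in closed form.
Three conventions matter:

* `0^0 = 1`, so a species absent from a reaction never affects its flux
  and the field is well defined at zero concentrations;
* negative concentrations produced transiently by an adaptive solver are
  passed through unmodified — clamping would destroy the smoothness the
  error estimators assume, and the tolerance machinery keeps excursions at
  the tolerance scale;
* the model is unit-agnostic: `K` must be expressed in units consistent
  with `X0` (concentrations and molecule counts both work, never mixed).
  Nothing in the package converts units.

Stoichiometric matrices are stored dense; the right-hand side additionally
caches a padded index representation of the nonzero entries of `A` so that
fluxes are computed with a handful of vectorized operations regardless of
`N`. Dense semantics are normative; the cache is an implementation detail.

## The two integrators

Both solvers are adaptive Runge–Kutta methods of order 5 with the standard
published coefficient sets, stored to full double precision
(`butcher_tableau()` exposes them; row sums reproduce the abscissae to
1e-12).

**DOPRI5** is the explicit Dormand–Prince 5(4) pair: 7 stages with the
first-same-as-last property, so an accepted step costs 6 right-hand-side
evaluations. The embedded fourth-order solution yields the local error
estimate, which is accepted when the scaled RMS norm

$$\mathrm{err} = \sqrt{\tfrac1N \textstyle\sum_i
  \left( e_i / (\varepsilon_a + \varepsilon_r
  \max(|x_i^{old}|, |x_i^{new}|)) \right)^2}$$

is at most 1. Output points are filled from the method's quartic dense
interpolant rather than by forcing steps onto the grid, preserving the
controller's natural step sequence.

**RADAU5** is the 3-stage Radau IIA collocation method: implicit, stiffly
accurate (the last stage *is* the step solution), strongly A-stable. The
nonlinear stage system is solved by simplified Newton iteration with the
Jacobian frozen at the step start; the `3N × 3N` Newton matrix
`I − h (A ⊗ J)` is factorized once per step attempt and reused across
iterations (at most 7; the iteration is declared failed when the
contraction factor reaches 0.99 or the projected error exceeds the Newton
tolerance, and the step is halved). A direct solve of the stacked system
was chosen over the classical complex-transformed `N`-sized solves: at the
model sizes this package targets the factorization is a negligible share
of the cost, and the direct form is simpler to verify. The local error is
the embedded lower-order combination of stage increments smoothed by one
solve with `(γ/h) I − J` (γ the real eigenvalue of the inverse stage
matrix), refined once with a re-evaluated right-hand side on the first or
a rejected step. Output points come from the cubic collocation polynomial
through the step endpoints and the two interior abscissae.

### Step-size control and other numerical choices

* Controller: `h_new = h · clamp(0.9 · err^(−1/5), 0.2, 10)` for DOPRI5
  and the same with upper clamp 8 for RADAU5. The `−1/5` exponent is used
  for both methods for uniformity, although the Radau error estimate is
  formally of lower order; this affects efficiency only, never accepted
  accuracy.
* Initial step: chosen by the standard magnitude heuristic (a step over
  which an explicit Euler increment stays near 1% of the solution scale)
  unless `h_init` is given; `h_fixed` disables the controller entirely,
  which is how the convergence-order checks run.
* Tolerances default to `eps_a = 1e-12`, `eps_r = 1e-6`, `max_steps =
  1e4` — the settings used throughout the package's own studies.
* Stiffness detection (DOPRI5): the scaled Lipschitz estimate
  `h · ‖f(y₁) − f(g₆)‖ / ‖y₁ − g₆‖` formed from the two trailing stages is
  compared against 3.25; fifteen consecutive flagged steps terminate the
  run with status `stiffness_detected`. The monitor is sampled every
  1000th accepted step and then on every step while suspicion persists.
  Sampling every step is a known false-positive trap: once a non-stiff
  system reaches equilibrium the controller grows `h` to the stability
  boundary, where `h·ρ` exceeds the threshold even though accuracy is not
  limited — the sparse cadence (that of the reference explicit-solver
  implementations) avoids retiring such runs.
* Degenerate grids: an output grid consisting only of the initial time
  returns the initial state with zero steps.
* A trajectory records `n_steps = n_accepted + n_rejected` and the solver
  used; failed runs keep the partial prefix of the grid and `NA`
  elsewhere.

## Stiffness classification and batch dispatch

Stiffness is decided per parameterization, not per model, because the
kinetic constants vary row by row: the spectral radius of the analytic
Jacobian at the row's initial state is estimated by power iteration (50
iterations maximum, convergence at 1e-3 relative, a fixed deterministic
start vector so results never depend on the caller's RNG). When the
iteration does not converge — typically a dominant complex pair — the
estimate falls back to a full eigen-decomposition and says so; it never
fails silently. Rows with spectral radius below the threshold (default
500) are integrated with DOPRI5, the others with RADAU5, and every DOPRI5
failure is re-run from `t = 0` with RADAU5 (`fallback_mask` records
which). Rows are embarrassingly parallel; the engine is sequential and
defines the result any parallel backend must reproduce exactly. A row
with invalid parameters is reported as such in its status and never
aborts the batch.

## The synthetic-network generator

The generator emulates the statistical shape of curated biochemical
networks: initial concentrations log-uniform on `[1e-4, 1)` and kinetic
constants log-uniform on `[1e-6, 10]` (both quantities disperse over
orders of magnitude in real models, hence uniform sampling in log space),
reactant multiplicities summing to at most 2 (zero-, first- and
second-order reactions; termolecular collisions are vanishingly rare) and
at most two product molecules. Reactant and product species are drawn
uniformly with replacement, so `2A` and `A + B` both occur; duplicate
reactions are allowed (their fluxes simply add). Whether pure-source
(zero-order) reactions should occur at all is ambiguous in practice, so
their emission is controlled by a flag defaulting to on. Generation is a
pure function of the spec's seed, which is recorded in the model metadata.

What the generator does *not* emulate: connectivity structure (hubs,
modularity), conservation relations, or any guarantee of bounded
dynamics — a random mass-action network is frequently autocatalytically
divergent. Study scripts therefore screen candidate seeds with a cheap
probe run and advance the seed deterministically until the dynamics stay
bounded over the study window; passing tests on such models demonstrates
solver and dispatch correctness, not biological realism.

Batches perturb each kinetic constant log-uniformly within ±25%:
`k' = exp(ln 0.75k + (ln 1.25k − ln 0.75k) · rnd)` with
`rnd ~ U[0, 1)`, so `k' ∈ [0.75k, 1.25k)` always and `log(k'/0.75k)` is
uniform after normalization — both properties are tested by
Kolmogorov–Smirnov at `α = 0.01` on 1e4 draws.

## Analysis workflows

**PSA-2D.** `psa_2d()` sweeps two axes — an initial concentration, or a
*set* of kinetic constants selected by a mask and *assigned* the axis
value (a mask models a macroscopic parameter that determines many
microscopic constants at once; assignment, not multiplication, is the
semantics) — over a Cartesian grid, dispatches the grid through the batch
engine in batches (default 512), and summarizes each trajectory. The
shipped summary is the mean oscillation amplitude: discard the leading
fraction of the grid (default 50%, a transient cut), find strict local
extrema, and average the drops from each maximum to the following
minimum; fewer than two maxima, or a total range below
`1e-6 · max(1, max)`, count as non-oscillating and return exactly 0. When
the settled regime of a non-oscillating run must land below that cutoff,
integrate tighter than `eps_r = 1e-6` — solver wiggle at the default
tolerance sits exactly at the cutoff scale.

**Sobol sensitivity analysis.** `saltelli_sample()` builds the classical
cross-sampled design (base matrices `A` and `B`, hybrids `AB_j`, and
`BA_j` when second-order indices are requested): `n_base · (2D + 2)` rows
with second order, `n_base · (D + 2)` without. The base matrices come
from a radical-inverse Halton sequence — written in-package because the
installed stack offers no quasi-random generator — which keeps the design
deterministic and low-discrepancy. Estimators are the standard
first-order form `S1_j = mean(y_B (y_{AB_j} − y_A)) / V` and the Jansen
total-order form `ST_j = mean((y_A − y_{AB_j})²) / (2V)`; confidence
half-widths are percentile bootstrap over the base sample (default 1000
resamples, 95% level). Zero output variance is reported as all-zero
indices with an explicit degeneracy flag. The implementation reproduces
the closed-form Ishigami first-order indices within its own bootstrap
CIs at `n_base = 1024`.

**Parameter estimation.** The objective is the relative distance between
simulated and target dynamics: the mean over all target points of
`|sim − target| / max(|target|, 1e-12)`; zero iff the match is exact,
`+Inf` for a failed simulation so optimizers penalize it. Two practical
notes from the package's own recovery experiments: (i) species whose
target trajectory falls to numerical zero make this objective
needle-shaped — their relative error explodes everywhere except at the
exact parameters — so recovery studies fit only species that stay above a
detection floor (1e-6 in the shipped experiments); (ii) kinetic
landscapes have genuine local minima, so the bundled reference optimizer
`fit_kinetics()` is a *multi-start* Nelder–Mead in log10 space
(deterministic ±1-decade offsets per free constant, low-discrepancy
starts beyond three free constants). It is deliberately minimal; any
global optimizer can be plugged in through the exposed fitness.

## Problem sizes used by the shipped studies

The test-suite and acceptance studies use: 100 random 8×8 models for the
right-hand-side oracle; 10×10 models for Jacobian and recovery studies;
a 64-species / 64-reaction network with 512 perturbed parameterizations
for the dispatch study (about a minute of CPU); `n_base = 1024` with 1000
bootstrap resamples for the Ishigami benchmark; grids of
`192 × 192 = 36864` cells for sweep-campaign arithmetic. These sizes were
chosen so each study finishes in seconds to a few minutes on one core
while still exercising every code path at realistic dimensions.

## Known limitations

* Mass-action kinetics only: Hill and Michaelis–Menten rate laws are out
  of scope (the SBML importer rejects them by structural analysis of the
  kinetic-law MathML rather than symbolic simplification, so an
  algebraically disguised mass-action law would also be rejected).
* The model-folder dialect (`left_side`, `right_side`, `c_vector`, `M_0`,
  `MX_0`, `c_matrix`, `t_vector`, `cs_vector`, `alphabet`; `cs_vector`
  0-based on disk) is this package's normative format; no export back to
  SBML.
* No event detection, root finding, mass matrices, or variable-order
  Radau; both methods are fixed at order 5.
* Execution is sequential; the batch contract (results independent of
  partitioning) is what a parallel backend would have to honor.
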