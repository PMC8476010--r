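# rbmsim

Deterministic simulation of mass-action reaction-based models (RBMs) in R,
with stiffness-aware solver dispatch for batches of independent
parameterizations, plus the analysis workflows built on top of batch
simulation: bi-dimensional parameter sweeps, variance-based Sobol
sensitivity analysis, and fitness-based parameter estimation.

## Who this is for

Systems biologists and modelers who describe a biochemical network as a
list of reactions — species, stoichiometries, kinetic constants — and need
to run *many* deterministic simulations of it: sweeping two parameters over
a grid, sampling initial conditions for a sensitivity analysis, or
evaluating thousands of candidate parameterizations during model
calibration. Biochemical ODE systems are routinely stiff (fast and slow
reactions coexist), and no single explicit solver survives that; this
package automates the choice per parameterization.

## The model and the method

An RBM with `N` species and `M` reactions is given by two `M x N`
non-negative integer stoichiometric matrices `A` (reactants) and `B`
(products), a vector `K` of `M` positive kinetic constants, and an initial
state `X0`. Under the law of mass-action the induced ODE system is

    dX/dt = (B - A)^T (K ∘ X^A),      (X^A)_i = Π_j X_j^(A_ij)

with the convention 0⁰ = 1. The package derives this right-hand side and
its analytic Jacobian automatically and integrates with one of two
adaptive order-5 Runge-Kutta methods:

* **DOPRI5** — the explicit Dormand–Prince 5(4) pair with embedded error
  estimation, quartic dense output and stiffness detection, for non-stiff
  parameterizations;
* **RADAU5** — the implicit 3-stage Radau IIA collocation method (stiffly
  accurate, strongly A-stable), stages solved by simplified Newton
  iteration, for stiff ones.

The batch engine estimates the spectral radius ρ of the Jacobian at the
initial state of every parameterization (power iteration with an
eigen-decomposition fallback); rows with ρ < 500 go to DOPRI5 and the rest
to RADAU5. Any row on which DOPRI5 gives up — stiffness detected, step
budget exhausted, step-size underflow — is transparently re-run from t = 0
with RADAU5. Defaults follow common practice: absolute tolerance 1e-12,
relative tolerance 1e-6, at most 1e4 steps.

The package also ships a synthetic network generator (log-uniform initial
concentrations in [1e-4, 1), log-uniform kinetic constants in [1e-6, 10],
reactions of order at most two on both sides), the ±25% log-uniform
kinetic perturbation used to build batches, readers/writers for a
plain-text model-folder dialect, and a minimal mass-action SBML importer.

## Worked example

```r
library(rbmsim)

# a random 6-species / 6-reaction mass-action network
m <- generate_rbm(synthetic_spec(n_species = 6, n_reactions = 6, seed = 7))
tidy(m)
#> # A tibble: 6 × 5
#>   reaction equation           order n_products          k
#>      <int> <chr>              <dbl>      <dbl>      <dbl>
#> 1        1 S3 -> S2 + S4          1          2 2.14
#> 2        2 S2 + S6 -> S3 + S6     2          2 0.000172
#> 3        3 S4 -> S2 + S4          1          2 0.00000378
#> 4        4 2 S6 -> S4 + S5        2          2 0.518
#> 5        5 S2 + S6 -> S2 + S4     2          2 1.95
#> 6        6 S3 -> 0                1          0 5.83

# four perturbed parameterizations (each constant jittered ±25% log-uniformly),
# solved with automatic stiffness dispatch
s     <- solver_settings(t_out = seq(0, 5, length.out = 6))
batch <- make_batch(m, R = 4, seed = 2)
res   <- run_batch(m, batch, s)
glance(res)
#> # A tibble: 4 × 7
#>   simulation classification   rho solver_used fallback status  n_steps
#>        <int> <chr>          <dbl> <chr>       <lgl>    <chr>     <int>
#> 1          1 nonstiff        7.89 DOPRI5      FALSE    success      68
#> 2          2 nonstiff        7.62 DOPRI5      FALSE    success      68
#> 3          3 nonstiff        8.85 DOPRI5      FALSE    success      71
#> 4          4 nonstiff        6.47 DOPRI5      FALSE    success      66
```

Every Jacobian spectral radius is far below the 500 threshold, so all four
rows went to the explicit solver and succeeded in ~70 adaptive steps each.
Per-row trajectories are tibble-friendly (`tidy(res$trajectories[[1]])`
gives `time`/`species`/`concentration` in long form) and plottable with
`autoplot()`.

A command-line front end (`inst/cli/rbmsim`) wraps the same functions as
`simulate`, `generate`, `convert` (SBML import), `psa2d` and `sobol`
subcommands over model folders on disk.

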