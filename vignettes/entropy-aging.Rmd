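---
title: "Entropy-based models of tissue degradation and biological age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based models of tissue degradation and biological age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entropage)
```

## The picture

A living tissue is an open nonequilibrium system: metabolism imports
negative entropy fast enough to hold the tissue's structure far from
equilibrium, but random errors in that same metabolism slowly erode the
structure, and entropy creeps upward over a lifetime. `entropage` turns
this picture into computable pieces at two timescales:

* a **fast** scale `\(\tau\)` (a characteristic metabolic time), on which
  a kinetic relaxation model describes the distribution of cells over
  depth and "velocity" in a tissue slab, and local entropy profiles
  separate a nonequilibrium "line of life" from the equilibrium "line of
  death";
* a **slow** scale `\(T\)` (the lifetime), on which a stochastic
  compartment simulation roughens and thins an initially smooth density
  profile, with the Kullback–Leibler divergence against the young
  baseline serving as an age statistic.

The two scales are tied together by an allometric invariant: across
mammals the lifetime holds roughly `\(10^9\)` heartbeats, the metabolic
time is about 30 heartbeat periods, and so the number of metabolic times
per lifetime is `\(N = T/\tau \sim 3\times10^7\)` regardless of body
size. `build_timescales()` does this arithmetic and checks its own
identities.

## Entropy functionals

Three functionals quantify disorder over discrete compartments.

**Statistical entropy.** `discrete_entropy()` computes
`\(-\sum_i p_i \log_b p_i\)` with the `\(0\log 0 = 0\)` convention. For a
normalized length-`\(n\)` input it lies in `\([0, \log_b n]\)`, and the
uniform distribution attains the maximum.

**Kullback–Leibler divergence.** `kl_divergence()` evaluates
`\(D(p\|q) = \sum_x p(x)\log_b\!\big(p(x)/q(x)\big)\)` between a young
baseline `\(p\)` and an older profile `\(q\)`. Two modes are provided
because the formula can be read over probabilities or over raw
densities:

* `"normalized"` (the default for trajectory statistics): both profiles
  are rescaled to sum to one, which guarantees `\(D \ge 0\)` with
  equality exactly at `\(p = q\)` (Gibbs' inequality) and makes the
  statistic sensitive to *shape*, not total mass;
* `"raw"`: the literal sum over unnormalized densities, which may be
  negative, but under which a single compartment with density ratio
  `\(10^9\)` contributes `\(\log_{10} = 9\)` — the lifetime
  order-of-magnitude anchor. Base 10 is therefore the default base.

Densities are clamped from below at a configurable floor (default
`1e-12`) before any ratio is formed, with a warning; an exact zero in
`\(q\)` against positive `\(p\)` is a support error, since no finite
divergence exists there.

**Combinatorial entropy.** `combinatorial_entropy()` returns
`\(\ln W\)` with `\(W = N!/\prod_i n_i!\)`, the multiplicity of
microstates consistent with occupation numbers `\(n_i\)`, computed via
`lgamma` so large `\(N\)` cannot overflow. It is zero when everything
occupies one cell (full cooperative order) and grows as occupation
spreads — a measure of lost cooperativity between parts of a system.
This multinomial form is the standard Boltzmann counting; it is the
package's chosen concrete definition for the qualitative notion of
combinatorial entropy as a cooperativity measure.

## The kinetic model

On the fast scale the cell population over a slab `\(x \in [0, L]\)`
(0 = basal layer, `\(L\)` = surface) is described by a distribution
`\(f(x, \xi)\)` obeying the stationary BGK-type equation

$$ \xi\,\frac{\partial f}{\partial x} = \frac{f_M[f] - f}{\tau}, $$

where `\(f_M\)` is the Maxwellian sharing `\(f\)`'s local density,
velocity and temperature (the self-consistent, standard BGK closure).
`solve_stationary_bgk()` discretizes this with first-order upwind sweeps
over a Gauss–Legendre velocity grid, alternated with moment/Maxwellian
updates under under-relaxation (factor 0.9), until the max-norm change
falls below `tol` (default `1e-8`, capped at `1e4` iterations; failure
raises an error carrying the residual history). Boundary conditions are
inflow Maxwellians at both walls — basal injection at `\(x=0\)` for
`\(\xi>0\)`, surface influx at `\(x=L\)` for `\(\xi<0\)` — the minimal
standard closure for a two-wall slab.

Local entropy is the velocity moment
`\(S(x) = -\int f\ln f\, d\xi\)` (`local_entropy_profile()`), and
`equilibrium_entropy_profile()` evaluates the same moment on the
nodewise Maxwellian. Because the Maxwellian maximizes `\(-\int f\ln f\)`
at fixed moments, the equilibrium profile dominates the nonequilibrium
one pointwise — the quantitative sense in which a living (nonequilibrium)
state carries *less* entropy than the dead (equilibrated) state with the
same macroscopic fields.

On the slow scale, spatially uniform relaxation

$$ \frac{\partial f_T}{\partial t_T} = \frac{f_{MT} - f_T}{T} $$

has the exact closed form
`\(f(t) = f_{MT} + (f_0 - f_{MT})e^{-t/T}\)` because BGK relaxation
conserves the moments that define the target; `relax_uniform()` returns
it, and entropy is provably non-decreasing along the trajectory (the
H-theorem: the path is a moment-preserving line toward the constrained
entropy maximizer, so concavity of `\(-\int f\ln f\)` forces
monotonicity). The same stationary operator run with relaxation time
`\(T\)` serves as the structural analogue on the lifetime scale;
`structural_state()` carries the coarse structural distribution with its
passive energy axis.

The age statistic integrates the entropy difference between an old and a
young profile over the old tissue's (thinner) depth:

$$ \Delta S = \int_0^{L_{old}} \big(S_{old}(x) - S_{young}(x)\big)\,dx, $$

computed by `entropy_age_delta()` with linear interpolation onto the
union mesh and the trapezoid rule — the quadrature consistent with
piecewise-linear profile data.

### Grids, units and numerical choices

Everything is dimensionless (no physical units are imposed on `\(f\)`).
Defaults: 64 uniform spatial nodes on `\([0,1]\)` and 32 Gauss–Legendre
velocity nodes on `\([-8, 8]\)`, all configurable via `phase_grid()`.
The node count must be even so that no node sits at `\(\xi = 0\)`, where
the stationary characteristic degenerates.

Gauss–Legendre quadrature of Maxwellians converges exponentially, but
two regimes deserve care. Narrow Maxwellians (`\(\theta \lesssim 0.3\)`)
need more than 32 nodes for moment accuracy below `1e-6`; and states
whose effective temperature pushes mass toward the velocity cut-off
(broad mixtures with large drift) are limited by *tail truncation*
rather than node count — on the default `\([-8,8]\)` domain,
moment conservation along `relax_uniform()` holds to about `1e-8` for
such states, and to `1e-11` or better once the domain is widened to
`\([-10,10]\)` with 48 nodes. The test suite exercises the strict
(`1e-9`) conservation property in that well-resolved regime.

The upwind scheme is first order in `\(\Delta x\)`: halving the mesh
halves the discretization error, and a coarse solution agrees with a
4×-refined reference to a few percent in the moment profiles at
`\(\tau = 0.1\)`. Two exact limits anchor correctness independently of
resolution: identical equilibrium wall states reproduce the global
Maxwellian to solver tolerance, and `\(\tau \to \infty\)` recovers free
streaming of the two wall Maxwellians.

## The aging simulation

`simulate_epithelium()` abstracts an aging epithelium as
`n_compartments` independent cell columns. Each iteration applies a fast
metabolic fluctuation — every column multiplied by `\(1+\epsilon\)`,
`\(\epsilon \sim U(-a, a)\)` — and, every `slow_every` iterations, a slow
thinning step subtracting an absolute decrement, clamped at the floor.
The multiplicative-uniform noise law keeps densities positive, is
scale-free, and is mean-preserving, so metabolism roughens without
draining; the absolute decrement is the simplest strictly monotone
thinning mechanism. Reference conditions (the defaults): 40
compartments, noise amplitude 0.1, thinning 0.002 per iteration with
`slow_every = 1`, 500 iterations, snapshots every 10, floor `1e-12`.
The literal biological scale separation (`\(N \sim 3\times10^7\)` fast
steps per slow step) is represented at desk scale by the smallness of
the per-step thinning rate; `slow_every` exposes the ratio explicitly
for those who want to widen it.

Each snapshot is scored by `kl_divergence()` against the iteration-0
young baseline (base 10, normalized mode by default) and by the derived
deviation `\(|D_t - 1|\)`. Under the reference conditions the ensemble
mean of `\(|D_t-1|\)` rises with iteration count — the aging trend — in
*either* divergence mode: in raw mode because the declining densities
swell the raw sum without bound, and in normalized mode because columns
pinned at the floor make the late profile sharply non-uniform relative
to the baseline, driving `\(D\)` well past 1. The trend is an ensemble
statistic (asserted over 20 seeds), not a per-seed monotonicity:
individual trajectories fluctuate, and early snapshots in normalized
mode can move `\(|D-1|\)` *down* from its initial value of 1 before the
growth takes over.

`generate_entropy_schematic()` produces the companion qualitative
picture: young and old entropy-versus-depth curves rising from a basal
baseline to a common dead-cell maximum at the surface, the old one
thinner, higher-based, noisier, and clipped to dominate the young curve
on their common support. It is an illustrative generator — a schematic
of the expected ordering, not a model of measured epidermal entropy —
and `entropy_age_delta()` on its output is positive by construction.

### What the generator does and does not emulate

The simulator reproduces the *mechanistic skeleton*: independent
compartments, fast mean-preserving chaos, slow systematic thinning, and
a divergence trajectory that grows in ensemble trend. It deliberately
omits spatial coupling between columns, keratinocyte lineage structure,
differentiation and desquamation kinetics, and any calibration to
histological data. Passing tests therefore certify the formalism's
internal consistency (Gibbs inequality, H-theorem, equilibrium
dominance, trend growth), not agreement with real skin measurements.

## Reproducibility and I/O

All randomness flows from explicit integer seeds: `simulate_epithelium()`
and `generate_entropy_schematic()` seed R's RNG once per run, so
identical configurations are bitwise reproducible. Profiles travel as
headed CSV (`position,value` for densities, `x,S` for entropy profiles)
written with 17 significant digits for lossless round trips;
divergence series as `iteration,kl,abs_dev_unit`; configuration echoes
and timescale sets as JSON. `make_fixtures()` bundles a seeded
reference set. A thin command-line front end over these functions ships
in `inst/cli/entropage.R` with `simulate`, `entropy`, `kinetic`,
`allometry` and `fixtures` subcommands; configuration is carried by
ordinary function arguments (`aging_sim_config()` for the simulator)
rather than a monolithic config file.

## Worked example

```{r example}
# allometry: the size-invariant degradation number
mouse <- build_timescales(0.1, 3, 1e9)
elephant <- build_timescales(2, 60, 1e9)
c(mouse = mouse$N, elephant = elephant$N)

# a short aging run
traj <- simulate_epithelium(aging_sim_config(n_iterations = 200, seed = 42))
round(traj$dev_series, 3)

# kinetic slab between two unequal-temperature walls
g <- phase_grid(nx = 32, nxi = 24)
f <- solve_stationary_bgk(macro_moments(1, 0, 0.5), macro_moments(1, 0, 1.5),
                          tau = 0.1, grid = g)
S <- local_entropy_profile(f, "life")
S_eq <- equilibrium_entropy_profile(f, "death")
min(S_eq$S - S$S)            # equilibrium dominance, everywhere >= 0
entropy_age_delta(S_eq, S)   # integrated entropy deficit of the living state
```

## Known limitations

* The kinetic model is 1-D in space and velocity, with linear BGK
  relaxation; there is no nonlinear collision operator, no
  time-dependent inhomogeneous solver, and no physical-unit calibration.
* The combinatorial-entropy definition is the standard multinomial
  multiplicity; other countings of cooperative arrangements would give
  different absolute values (though the same qualitative growth).
* The divergence-versus-iteration trajectory is qualitative: its shape
  depends on the noise law, thinning law and floor, none of which are
  fitted to data.
* The inflow-Maxwellian boundary closure for the stationary slab is the
  minimal standard choice; other wall models (diffuse reflection,
  partial accommodation) are out of scope.
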