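---
title: "Surrogate-assisted optimization of stent expansion: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted optimization of stent expansion: models, choices, limits}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentkrig)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical and design choices
made where the design was genuinely open, and what the bundled synthetic
simulator does and does not tell you about real stent mechanics.

## The optimization problem

A balloon-expandable stent is described by seven design variables: four main
strut widths `W1..W4` (0.22–0.34 mm), the bridge-strut width `W5`
(0.2–0.3 mm), the strut thickness `T` (0.1–0.14 mm) and the balloon length
`L` (4.5–6.5 mm).  Two expansion-performance metrics are minimized jointly:

* the **dogboning ratio** `DR = (d_distal − d_proximal)/d_proximal` of the
  radial displacements at full expansion — positive when the distal end
  flares first, negative when the proximal end does; uniform expansion gives
  zero, so the objective uses `|DR|`;
* the **radial elastic recoil** `RER`, the mean fractional radius loss at
  four bridge-strut points of interest between the fully-loaded and unloaded
  states.

Every design is compared at the same clinical endpoint: the inflation
pressure is calibrated (by bisection, `find_pressure()`) so that the
post-recoil proximal diameter equals 4.54 mm, the lumen of a healthy
reference artery.  Without this calibration the two metrics would partly
measure "how hard the balloon was pushed" rather than the geometry.

The two metrics have different scales (`|DR|` up to a few tenths, `RER` a
few hundredths), so the weighted-sum objective first maps each to `[0, 1]`
by its extrema **over the evaluated samples** and then weights them with
`ω = 0.5` (`scalarize()`).  Two consequences shape the implementation:

* the normalization bounds move as the archive grows, so all archive
  objectives are recomputed against fresh bounds before every surrogate
  refit — fitting against stale objectives would make the surrogate
  internally inconsistent;
* a design outside the archive's metric range can scalarize outside
  `[0, 1]`; values are deliberately not clipped, since clipping would
  flatten the surrogate exactly where improvement happens.

When all archive values of one metric coincide (possible on tiny archives)
its normalization denominator vanishes; that term is defined as 0 with a
warning, keeping the objective finite.

## Design of experiments: the modified rectangular grid

The initial sample comes from a rectangular (full factorial) grid with
`q_j` levels per dimension, modified in two ways: the range of each variable
is first narrowed by half a grid step at the top
(`û_j = u_j − (u_j − l_j)/(2(q_j − 1))`), and each point then receives an
independent non-negative per-dimension displacement
`(α/2)(u_j − l_j)/(q_j − 1)` with `α ∈ [0, 1]`.  The reserved margin equals
the maximal displacement, so points stay inside the box; and because two
distinct cells differ by at least one full narrowed step while displacements
differ by at most half an original step, any two points are at least
`min_j (u_j − l_j)/(2(q_j − 1)) (1 − 1/(q_j − 1))` apart
(`min_distance_bound()`, verified by brute force in `validate_spacing()`).

Two details are underdetermined and were decided once:

* **The `α` distribution.**  The displacement fraction is described as both
  supported on `[0, 1]` and normally distributed, which no distribution
  satisfies exactly; the package draws `α` from a Normal(0.5, 1/6) truncated
  to `[0, 1]` (via inverse CDF, so it is fully seed-driven), honouring both
  the support and the family.
* **Level counts and subsetting.**  Drawing 30 points from a 7-dimensional
  grid requires choosing `q_j` and a subsetting rule, neither of which is
  canonical.  The default is `q_j = 2` (a 128-cell grid) with a seeded
  greedy maximin-distance selection of distinct cells: starting from a
  random cell, each subsequent cell maximizes its minimum distance to the
  selected set (earliest index on ties, for determinism).  Distinct cells
  preserve the spacing guarantee; maximin preserves space-filling.

Distances are computed in the native units of the variables, matching the
per-dimension form of the bound; a unit-cube-scaled distance is available
as a diagnostic only.

## The Kriging surrogate

The surrogate is ordinary Kriging: a constant trend `β` plus a zero-mean
stationary Gaussian process with variance `σ²` and Gaussian correlation
`Π_l exp(−θ (x_l^i − x_l^j)²)`.  Design choices:

* **Trend basis.**  Constant (ordinary Kriging).  The regression vector `f`
  acts as a ones-vector throughout; a richer trend buys little inside a
  bounded box with adaptive sampling.
* **θ dimensionality.**  A single shared `θ` by default, with per-dimension
  `θ` behind `per_dim_theta = TRUE`.  Inputs are scaled to the unit cube
  first (the scaling bounds ride along on the model object), so a shared
  `θ` is meaningful across dimensions and predictions accept original-space
  points.
* **Estimation.**  Given `θ`, `β̂` and `σ̂²` have closed generalized-least-
  squares forms; `θ̂` minimizes the concentrated criterion
  `ψ(θ) = |R|^{1/n} σ̂²(θ)` by seeded multistart L-BFGS-B in `log θ` over
  `θ ∈ [1e-3, 1e2]` (10 starts).  The two sample-size symbols appearing in
  the criterion and in `σ̂²` are both taken as the number of training
  points.
* **Predictor.**  The best-linear-unbiased-predictor mean
  `ŷ(x*) = β̂ + r(x*)ᵀ R⁻¹(y − β̂f)` and the standard constant-trend MSE
  `σ̂²[1 − rᵀR⁻¹r + (1 − fᵀR⁻¹r)²/(fᵀR⁻¹f)]`, clamped at zero when
  cancellation makes it marginally negative.

### Numerical safeguards

Gaussian-kernel correlation matrices are famously ill-conditioned.  The
package layers four defences, each with a specific failure mode in mind:

1. **Nugget ladder.**  If Cholesky factorization fails, a diagonal nugget
   escalates through `0, 1e-12, 1e-10, 1e-8`.  Crucially, the *search* over
   `θ` is evaluated at one fixed nugget (failures are penalized, and the
   nugget escalates only between whole search attempts): mixing nugget
   levels inside one likelihood surface creates a spurious minimum at tiny
   `θ`, where a singular `R` "rescued" by regularization shrinks `|R|^{1/n}`
   faster than `σ̂²` grows.
2. **Conditioning guard.**  `θ` values whose Cholesky pivot ratio falls
   below `1e-6` (condition number beyond ~1e12) are rejected during the
   search — `ψ` keeps decreasing into that region for some data, but the
   resulting "fit" is numerical noise.
3. **Interpolation safeguard.**  After fitting, the model must reproduce its
   own training responses through the same arithmetic `predict()` uses (a
   backward-stable solve masks forward error when `R` is near-singular and
   the dual weights are huge).  If it cannot, the offending low-`θ` region
   is excluded and the search repeats, up to eight times.
4. **Honest failure.**  Responses that are mutually inconsistent at
   near-duplicate inputs (e.g. noisy data at points closer than the
   duplicate tolerance) cannot be interpolated in double precision by any
   Kriging implementation; the fit then warns rather than pretending.

Degenerate inputs degrade gracefully: a single training point or a constant
response yields `σ̂² = 0` and a constant predictor (with a warning in the
constant case), and expected improvement is exactly zero there.

## Expected improvement and its maximization

`EI(x) = σ(x)[uΦ(u) + ϕ(u)]` with `u = (y_min − ŷ(x))/σ(x)`, and `EI = 0`
where the predictive variance vanishes — triggered numerically when
`mse < 1e-12 σ̂²`, a proxy for exact zero that fires at training points.
The maximizer runs seeded multistart L-BFGS-B in the unit cube (the best
training point plus 63 uniform starts by default), returns the best local
optimum, and keeps the whole ranked candidate list so the optimizer can fall
back to the next-best candidate when an evaluation fails.  A surrogate with
zero variance everywhere returns the best start flagged degenerate.

## The adaptive loop

Each iteration refreshes the normalization bounds and archive objectives,
refits the surrogate, evaluates the EI-maximal candidate, and tests three
convergence criteria **conjunctively** (the conservative reading of a
stopping rule whose prose allows "and/or"):
`EI_k/(Y_max − Y_min) ≤ Δ1`, `|f_k − f_{k−1}| ≤ Δ2`, `|f_k − ŷ_k| ≤ Δ3`,
all inclusive.  Defaults are `Δ1 = 1e-3`, `Δ2 = 1e-4`, `Δ3 = 1e-4` with a
budget of 50 infill evaluations; no canonical values exist, so all are
exposed in `ego_tolerances()`.  The incumbent is the archive record with
minimal objective under the current bounds, earliest record on ties.
By default the surrogate models the scalarized objective directly (one
model); an alternative mode fitting separate `|DR|` and `RER` surrogates and
scalarizing at prediction time exists behind `two_surrogates = TRUE` for
comparison.  The reference geometry is included in the initial archive as a
flagged seed record alongside the 30 MRG samples, so comparisons against it
never extrapolate the normalization bounds.

Evaluator failures are first-class: the failed design is recorded, the
candidate skipped, and the loop continues down the EI ranking; every
evaluator call — including failures — counts against the budget.

## The synthetic expansion simulator

The bundled evaluator (`stent_sim_config()`, `simulate_expansion()`) is an
**invented analytic stand-in** for a finite-element balloon-stent analysis.
It exists so the full loop is runnable and testable; it claims no mechanical
fidelity.  Its structure encodes the qualitative physics the optimization
exploits:

* expansion is pressure over an aggregate stiffness increasing in the strut
  widths and thickness, so stiffer designs need more calibrated pressure;
* the recoil fraction decays exponentially in the bridge-strut width `W5`
  (more radial force, less recoil) and mildly increases for slimmer, thinner
  struts — the recoil side of the trade-off;
* dogboning grows with a stiffness-like group and has an interior minimum in
  the balloon length, and increases with `W5` — the dogboning side of the
  trade-off;
* loading POI radii carry a fixed small spread and per-POI recoil
  modulation (mean one), so the recorded `RER` equals the model recoil
  fraction exactly; all radii shrink by the same factor on unloading, so
  the post-recoil dogboning keeps the sign of the full-expansion value.

Coefficients were fixed once so that the reference geometry
(`W = 0.28×4, 0.249 mm`, `T = 0.12 mm`, `L = 5.8 mm`) evaluates to
`DR = 0.0622`, `RER = 0.0178` at a calibrated 1.87 MPa, and so that metric
ranges over the design box land in realistic territory (`|DR|` up to ~0.4,
`RER` 0.013–0.023, pressures 1–2.5 MPa).  Optional Gaussian response noise
(`noise_sd`, default 0) exercises surrogate robustness; pressure calibration
always uses the noiseless model so the endpoint stays well-defined.

**What passing tests show — and do not.**  Green tests demonstrate that the
optimization machinery (DOE, surrogate, infill, convergence, reporting) is
correct and that it resolves the encoded trade-off on a smooth
seven-variable response.  They say nothing about contact mechanics,
plasticity, balloon folding, vessel or plaque interaction, or any real
stent: the simulator is smooth and cheap where finite-element responses are
expensive and only piecewise-smooth, and its optimum is a property of the
invented coefficients, not of any physical stent.

## Problem sizes and budgets

The test suite and the acceptance script run the method at desk scale,
chosen as the smallest sizes at which each property is meaningfully
exercised: 50 random surrogate fits up to `n = 40, m = 7` for interpolation;
100 Monte-Carlo checks of the EI closed form at 10⁶ draws each; the spacing
guarantee over 100 seeds on a 3-dimensional grid; correlation-parameter
recovery on 20 exact GP draws (`n = 40, m = 2`); loop convergence on a 1-D
quadratic (5 + 20 evaluations) and a rescaled 2-D multimodal benchmark
(10 + 40 evaluations) over 10 seeds against dense-grid oracles; and the full
stent run with 30 MRG samples plus the reference design and a 25-evaluation
infill budget.

## Known limitations

* The weighted-sum scalarization finds one compromise design per weight; it
  cannot reach non-convex parts of a Pareto front.  Pareto construction and
  constrained recasting are out of scope.
* A single shared `θ` assumes comparable response smoothness across scaled
  dimensions; `per_dim_theta = TRUE` relaxes this at extra fitting cost.
* Ordinary Kriging interpolates: genuinely noisy evaluators need a larger
  nugget (exposed) or a regression formulation (out of scope), and
  near-duplicate designs with inconsistent responses are rejected or warned
  about rather than smoothed.
* The archive-adaptive normalization makes objective values comparable only
  within one run; cross-run comparisons should use the raw metrics.
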