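---
title: "Models and methods: social feedback in collective foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: social feedback in collective foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsignal)
```

## The model

A colony of foragers distributes itself over `n` forage patches with
qualities `q_i > 0`. Each individual is either uncommitted (`U`) or committed
to one patch. The desired outcome is the quality-proportional target
allocation

```
x_i* = q_i / sum_j q_j
```

defined over committed foragers. Four reaction classes move individuals
between commitment states, all conserving the total population:

| reaction | scheme | rate law | present in |
|---|---|---|---|
| discovery | `U -> i` | `q_i x_U` | all variants |
| abandonment (leak) | `i -> U` | `a x_i` | all variants |
| recruitment | `U + i -> 2i` | `r_i x_U x_i` | social variants |
| stop signalling | `i + i -> U + i` | `z x_i^2` | negative feedback |

Stop signalling is *self-inhibition*: an individual committed to patch `i`
makes another forager on the same patch uncommitted. Cross-patch inhibition
is deliberately not generated. The three shipped variants are:

* **positive_only** — quality-insensitive recruitment `r_i = rho`, no stop
  signal;
* **negative_feedback** — quality-sensitive recruitment `r_i = rho q_i` and
  a quality-insensitive stop signal `z > 0`;
* **asocial** — discovery and abandonment only (`r_i = 0`, `z = 0`), the
  ancestral baseline.

Both engines consume the same compiled reaction table. In the
infinite-population limit the mass-action ODE for the committed fractions is

```
dx_i/dt = q_i x_U - a x_i + r_i x_U x_i - z x_i^2 ,   x_U = 1 - sum_j x_j .
```

The finite-population master equation is simulated exactly with Gillespie's
direct method on integer counts `(X_U, X_1, ..., X_n)` with `sum X = S`.

## Parameters

All rates are per abstract model time unit; no mapping to seconds is
attempted. The canonical scenario (returned by `canonical_parameters()`)
uses the reference values: qualities `(0.75, 0.5, 0.25)`, abandonment
`a = 1e-3`, average recruitment strength `r = 100`, stop-signal strength
`z = 3.1`, population size `S = 200`, evaluation time 400 (three-patch
scenario) or 1000 with qualities `(0.75, 0.5)` (two-patch accuracy
scenario). These are the printed parameters of the reference study
conditions and are not tuned here.

Two derived quantities matter throughout:

* **Recruitment equalisation.** To compare variants fairly, the recruitment
  coefficient is set so recruitment happens on average at the same rate
  `r` in both social variants: `rho = r` (positive only) and
  `rho = r / mean(q)` (negative feedback), with the unweighted arithmetic
  mean over patches. The supplementary formula behind the published
  equalisation is not available in the source text; the unweighted mean is
  the plainest reading of "on average at the same rate", it is recorded in
  all output metadata, and a target-weighted alternative could be swapped
  behind the same interface.
* **The exactness point `z = a rho`.** Substituting a proportional state
  `x_i = c q_i`, `x_U = a c` into the rate equations leaves
  `c^2 q_i^2 (a rho - z)`, so at `z = a rho` the committed allocation is
  *exactly* proportional to quality (conservation then gives
  `c = 1/(a + Q)`, `Q = sum q_j`). The canonical `z = 3.1` is 15.5 times
  this point (`a rho = 0.2`): it is treated as a given of the scenario, not
  as our optimiser's output, and is consistent with the speed-robustness
  trade-off (stronger stop signalling buys speed at the cost of accuracy).

The models are meant for the biological regime where social recruitment is
far more efficient than independent discovery (`r_i >> q_i`). This is not
enforced mathematically; `rate_parameters()` only emits a note when it is
violated.

## Two error measures

`r2_error()` is the raw squared distance of the committed fractions from
the target, `sum_i (x_i - x_i*)^2`, excluding the uncommitted fraction.
This is the reported error: the trade-off curves, the per-run SSE
(`ensemble_sse()`, computed on fractions `counts/S` so values are
comparable across `S`), and convergence detection all use it.

Because the target sums to 1 while an equilibrium always retains a small
uncommitted residual, the raw distance has an irreducible floor
`(a/(a+Q))^2 sum x*^2` even when the allocation is perfectly proportional
(about `1.7e-7` at canonical parameters). `allocation_r2()` therefore
renormalises the committed fractions by their own sum before comparing:
it is exactly zero at `z = a rho`, and is the objective of
`optimise_z(objective = "min_error")`, whose golden-section search on
`log z` recovers `a rho` to high accuracy — a self-test of the closed form.

## Numerical choices

* **Stiffness.** The canonical rates span five orders of magnitude
  (`a = 1e-3` against `rho q ~ 1e2`), and the positive-only model's slow
  transients are near-critical (growth rate `rho x_U - a` close to 0).
  Integration uses `deSolve::lsoda` with the analytic Jacobian
  (`jactype = "fullusr"`) and tight defaults `rel_tol = 1e-10`,
  `abs_tol = 1e-12`. States more negative than `-1e-9` abort the
  integration with an error rather than being clipped.
* **Conservation.** The uncommitted fraction is eliminated
  (`x_U = 1 - sum x`), so the system has `n` equations and the Jacobian
  spectrum is free of the trivial zero mode of the full simplex.
* **Fixed points.** Closed forms exist for the positive-only variant
  (`x_i = q_i u/(a - rho u)` with `u` the smaller positive root of
  `rho u^2 - (rho + a + Q) u + a = 0`) and the asocial variant
  (`x_U = a/(a+Q)`, `x_i = q_i x_U / a`). The negative-feedback fixed point
  is located by long-time integration followed by damped Newton iteration
  with the analytic Jacobian. All routes are polished to residual
  `max |dx/dt| < 1e-12`; only interior fixed points are reported, and
  stability is classified from the Jacobian eigenvalues (analytic
  differentiation, never finite differences — a finite-difference oracle
  appears only in the tests).
* **Convergence time** is the first *sustained* passage of the squared
  distance below the threshold (`1e-4` by default): the earliest time after
  which the distance stays below the threshold up to the horizon, evaluated
  on a logarithmic grid of 200 points per decade and refined by log-log
  interpolation. First-crossing detection would be fooled by tangential
  grazing. The reference allocation is an argument: the Eq-style target for
  the perturbation-delay experiment (whose fixed points lie within `1e-4`
  of it), the variant's own fixed point for the trade-off sweep, where
  large `z` pushes the fixed point further than `1e-4` from the target and
  a target-based time would be undefined.
* **SSA conventions.** Social channels scale as `(r_i/S) X_U X_i` and
  `(z/S) X_i (X_i - 1)` (ordered pairs, no 1/2 symmetry factor), which
  reproduces the ODE terms `r_i x_U x_i` and `z x_i^2` exactly as `S` grows;
  mutual consistency of the two engines is the testable contract, and the
  microscopic convention is stated here because observable `z`-dependent
  quantities could shift by an O(1) factor under a different one. The
  direct method draws two random numbers per event from R's RNG, so
  `set.seed()` gives bit-for-bit reproducibility. States are recorded by
  left-hold sampling on a fixed grid (401 points by default),
  right-continuous at event times; full event logs are optional.
* **Seeds.** Ensemble run `k` uses seed `master_seed + k - 1`, recorded in
  the output. Because the stream depends only on `(master_seed, k)`,
  variant comparisons reuse one master seed so variance orderings are not
  confounded by sampling luck (paired-seed design).

## Design choices on open points

* **Trade-off sweep conventions.** Along the `z` sweep the convergence time
  is measured to the fixed point (see above) and the error is the raw
  distance of the fixed point from the target. Along the recruitment
  (`rho`) sweep the stop-signal strength is held at a fixed *relative*
  strength `z/(a rho) = 15.5` (the canonical ratio): the exactness point
  `a rho` sets the natural scale of `z`, and sweeping `rho` at fixed
  absolute `z` would conflate stronger recruitment with a drift toward the
  slow exactness regime — under the fixed-ratio convention both the error
  and the convergence time fall monotonically as recruitment strengthens.
* **Adaptation.** Re-convergence after an environmental change is assessed
  from random *committed* states (Dirichlet allocation of 95% of the
  colony): adaptation concerns a colony that is already deployed. The
  informative statistic is the adaptation time normalised by each variant's
  own from-scratch convergence time: near 1 with negative feedback
  (constant convergence time regardless of the initial state), above `1e4`
  for positive feedback alone, which can only reallocate committed foragers
  through the slow leak. Raw coefficients of variation are also reported,
  but within any one family of random committed states the positive-only
  times are uniformly slow, so a CV contrast between variants understates
  the effect.
* **Initial conditions.** The default initial state is the fully
  uncommitted colony for both engines. The perturbed state of the
  perturbation-delay experiment commits 5% of the colony to the worst
  patch (`x_1 = x_2 = 0`, `x_3 = 0.05`). The source text does not print the
  exact symmetric initial condition of its trajectory panels;
  fully-uncommitted is assumed and the five-orders-of-magnitude delay is
  reported under this assumption.
* **Boxplots** use the classical Tukey definition (hinges, 1.5 IQR
  whiskers, outliers beyond), matching `grDevices::boxplot.stats`. Both
  per-patch and pooled statistics can be derived from the exported per-run
  tables, since the reference figures do not state which pooling they use.

## What the simulations do and do not emulate

The generator reproduces demographic noise — fluctuations of order
`1/sqrt(S)` from the finite number of foragers — under well-mixed,
memoryless interactions with static patch qualities within a run.
Environmental change is composed at the experiment level by switching
quality vectors between integration segments. Not modelled: spatial
structure and travel times, time-correlated signalling, quality
measurement noise, and any fitness interpretation. Passing tests therefore
demonstrate properties of the reaction-network model, not of real colonies.

## Problem sizes

Desk-scale defaults keep every experiment reproducible in minutes on one
CPU: ensembles of 200 runs (down from the reference 1000; orderings and
interval checks remain valid at this size and all comparisons are
paired-seed), populations `S = 200` (up to `1e4` for the mean-field-limit
check), horizons of 400-1000 time units for the SSA and up to `1e8` for
the stiff perturbation-delay integration. The trade-off sweeps use 10-12
`z` values and 4 `rho` values.

## Known limitations

* The negative-feedback fixed point is found numerically; for extreme
  parameters (e.g. `z` thousands of times `a rho`) the long-time
  integration start point may sit near the simplex boundary and Newton
  refinement can fail with an error rather than returning a boundary point.
* `convergence_time()` resolves crossings to about 1% (grid density);
  comparisons across decades are unaffected.
* The exact objective behind the published `z = 3.1` is not reproducible
  from the available text; the package reproduces its *consequences*
  (variance suppression, trade-off position) and exposes the trade-off
  weight `lambda` in `optimise_z()` for users to explore.
* Only the three canonical variants (plus the two recruitment families of
  `rate_function_search()`) can be built; this is not a general
  chemical-reaction-network DSL.
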