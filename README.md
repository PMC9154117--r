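# stopsignal

Social-insect colonies regulate collective foraging with positive feedback
(recruitment: waggle dances, tandem running, trail pheromone) and, less
conspicuously, negative feedback (stop signals, negative pheromone
markers). `stopsignal` simulates a family of commitment-state reaction
models of this process to ask what the negative signal buys. In an
infinitely large colony both feedback architectures steer the foragers to
the same quality-proportional allocation across patches — but in a finite
colony of `S` individuals, demographic noise makes the two very different:
with positive feedback alone the colony frequently locks onto allocations
far from the target, while adding stop signalling suppresses that variance
by two orders of magnitude, at the cost of a tunable speed–robustness
trade-off.

The package is aimed at researchers in collective behaviour and
theoretical biology who want a reproducible, exactly seeded implementation
of both the mean-field and the master-equation pictures of this system.

## The model

A colony of `S` foragers distributes itself over `n` patches with
qualities `q_i`. Each individual is uncommitted (`U`) or committed to one
patch `i`; the desired allocation is `x_i* = q_i / Σ_j q_j`. Four reaction
classes act (rates in parentheses):

* discovery `U → i` (`q_i`), abandonment `i → U` (`a`) — both variants;
* recruitment `U + i → 2i` (`r_i`) — `r_i = ρ` without negative feedback,
  `r_i = ρ q_i` with it, `ρ` set so both variants recruit at the same
  average rate `r`;
* stop signalling `i + i → U + i` (`z`) — self-inhibition, negative
  feedback only.

The mean-field limit `dx_i/dt = q_i x_U − a x_i + r_i x_U x_i − z x_i²`
(`x_U = 1 − Σ x_j`) is integrated with a stiff adaptive solver and solved
for fixed points and stability; finite colonies are simulated exactly with
Gillespie's direct-method SSA (Rcpp inner loop). At `z = aρ` the
negative-feedback equilibrium allocation is *exactly* proportional to the
qualities; larger `z` converges faster but lands further from the target.

## Worked example

```r
library(stopsignal)

sys <- foraging_model("negative_feedback", qualities = c(0.75, 0.5, 0.25),
                      a = 1e-3, r = 100, z = 3.1)
find_fixed_point(sys)
#> Fixed point (negative_feedback): 0.49269724, 0.32998548, 0.16723057  x_U = 0.01008671
#>   residual: 1.33e-15 | stable: TRUE
#>   eigenvalue real parts: -118.1, -1.201, -0.5894
```

The stable equilibrium sits close to the target `(0.5, 0.333, 0.167)`:
at `z = 3.1` (15.5 times the exactness point `aρ = 0.2`) the colony trades
a small allocation error for fast convergence. The finite-population
comparison at `S = 200`, 200 paired-seed runs per variant, evaluated at
time 400:

```r
cmp <- variance_comparison(canonical_parameters(), n_runs = 200, master_seed = 1)
cmp$positive_only$variance      # 0.0654  0.0533  0.0305
cmp$negative_feedback$variance  # 0.00125 0.00100 0.000641
cmp$variance_ratio              # 0.0192  0.0188  0.0210
```

Stop signalling cuts the per-patch variance of the committed fractions
fifty-fold. The price of positive feedback alone is extreme sensitivity to
initial conditions: committing just 5% of the colony to the worst patch
before starting delays mean-field convergence by more than six orders of
magnitude:

```r
perturbation_delay()
#> $t_symmetric  0.08209
#> $t_perturbed  296706
#> $log10_ratio  6.558
```

Other entry points: `sse_comparison()` (accuracy distributions at
convergence), `tradeoff_sweep()` (speed–robustness curves over `z` and
`ρ`), `optimise_z()` (stop-signal tuning), `rate_function_search()`
(which recruitment function suits each architecture),
`adaptation_experiment()`, `asocial_baseline()`,
`deviation_probability()`, and a command-line front end:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/forage.R", package = "stopsignal"))') \
    experiment variance --runs 200 --seed 1 --outdir out/
```

See `vignette("foraging-feedback-models")` for the model assumptions,
numerical choices and design decisions.

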