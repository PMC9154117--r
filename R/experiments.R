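#' Canonical three-patch scenario parameters
#'
#' The reference scenario used throughout: three patches with qualities
#' (0.75, 0.5, 0.25), abandonment `a = 1e-3`, average recruitment strength
#' 100, stop-signal strength `z = 3.1`, population size `S = 200`,
#' evaluated at time 400. The two-patch accuracy scenario drops the third
#' patch and evaluates at time 1000.
#'
#' @param n_patches 3 (default) or 2.
#' @return Named list of scenario parameters.
#' @export
canonical_parameters <- function(n_patches = 3) {
  if (n_patches == 3) {
    list(qualities = c(0.75, 0.5, 0.25), a = 1e-3, r = 100, z = 3.1,
         S = 200, t_end = 400, t_eval = 400)
  } else if (n_patches == 2) {
    list(qualities = c(0.75, 0.5), a = 1e-3, r = 100, z = 3.1,
         S = 200, t_end = 1000, t_eval = 1000)
  } else {
    stop("canonical scenarios have 2 or 3 patches", call. = FALSE)
  }
}

both_variants <- function(p) {
  list(
    positive_only = foraging_model("positive_only", p$qualities,
                                   a = p$a, r = p$r),
    negative_feedback = foraging_model("negative_feedback", p$qualities,
                                       a = p$a, r = p$r, z = p$z)
  )
}

#' Sensitivity of convergence speed to the initial state
#'
#' Measures, for the positive-only model, the mean-field convergence time
#' to the quality-proportional target from (i) the symmetric fully
#' uncommitted state and (ii) a perturbed state in which a small fraction
#' of the colony starts committed to the worst patch (`x_n = perturbation`,
#' all other patches empty). The positive-only dynamics amplify whichever
#' patch is populated first, so the perturbed start delays convergence by
#' many orders of magnitude.
#'
#' @param qualities Patch qualities (default canonical three-patch set).
#' @param a,r Abandonment rate and average recruitment strength.
#' @param perturbation Initial committed fraction on the last patch.
#' @param tol Convergence threshold on the squared distance (default 1e-4).
#' @param horizon Maximum time searched.
#' @return List with `t_symmetric`, `t_perturbed` and `log10_ratio`.
#' @export
perturbation_delay <- function(qualities = c(0.75, 0.5, 0.25), a = 1e-3,
                               r = 100, perturbation = 0.05, tol = 1e-4,
                               horizon = 1e8) {
  sys <- foraging_model("positive_only", qualities, a = a, r = r)
  n <- length(qualities)
  init_pert <- c(rep(0, n - 1L), perturbation)
  t_sym <- convergence_time(sys, tol = tol, horizon = horizon)
  t_pert <- convergence_time(sys, init = init_pert, tol = tol,
                             horizon = horizon, check_fixed_point = FALSE)
  list(t_symmetric = t_sym, t_perturbed = t_pert,
       log10_ratio = delay_log10(t_pert, t_sym))
}

#' Paired-variant finite-population comparison
#'
#' Runs SSA ensembles of both social variants with the same derived seed
#' stream (so variance orderings are not confounded by sampling luck) and
#' summarises the committed fractions at the evaluation time: per-patch
#' ensemble mean, standard error, variance, and Tukey boxplot statistics,
#' alongside the quality-proportional target.
#'
#' @param params Scenario list as produced by [canonical_parameters()].
#' @param n_runs Runs per variant.
#' @param master_seed Master seed shared by the two ensembles.
#' @param keep_ensembles Return the raw ensembles as well?
#' @return List with `target`, per-variant summaries (`mean`, `se`,
#'   `variance`, `sse`, `boxplot`), `variance_ratio`
#'   (negative-feedback / positive-only, per patch) and optionally
#'   `ensembles`.
#' @export
variance_comparison <- function(params = canonical_parameters(),
                                n_runs = 200, master_seed = 1,
                                keep_ensembles = FALSE) {
  systems <- both_variants(params)
  target <- target_distribution(systems[[1]]$environment)
  ens <- lapply(systems, run_ensemble, S = params$S, n_runs = n_runs,
                t_end = params$t_end, master_seed = master_seed)
  summarise <- function(e) {
    fr <- ensemble_fractions(e, params$t_eval)
    list(mean = colMeans(fr),
         se = apply(fr, 2L, function(v) sd(v) / sqrt(length(v))),
         variance = apply(fr, 2L, var),
         sse = ensemble_sse(e, target, params$t_eval),
         boxplot = apply(fr, 2L, tukey_stats))
  }
  out <- list(target = target,
              positive_only = summarise(ens$positive_only),
              negative_feedback = summarise(ens$negative_feedback))
  out$variance_ratio <- out$negative_feedback$variance /
    out$positive_only$variance
  if (keep_ensembles) out$ensembles <- ens
  out
}

#' Accuracy comparison at convergence (two-patch scenario)
#'
#' Distribution of the per-run sum of squared errors from the target at a
#' late evaluation time, for both social variants with paired seeds.
#'
#' @inheritParams variance_comparison
#' @return List with per-variant `sse` vectors, their medians and Tukey
#'   boxplot summaries.
#' @export
sse_comparison <- function(params = canonical_parameters(2), n_runs = 200,
                           master_seed = 1) {
  systems <- both_variants(params)
  target <- target_distribution(systems[[1]]$environment)
  out <- lapply(systems, function(sys) {
    e <- run_ensemble(sys, S = params$S, n_runs = n_runs,
                      t_end = params$t_end, master_seed = master_seed)
    s <- ensemble_sse(e, target, params$t_eval)
    list(sse = s, median = median(s), boxplot = tukey_stats(s))
  })
  out$target <- target
  out
}

#' Speed-robustness trade-off sweep
#'
#' For the negative-feedback model (mean-field engine only), sweeps the
#' stop-signal strength `z` (and optionally the recruitment coefficient
#' `rho` at fixed `z`) and reports, per grid point, the fixed-point squared
#' distance from the target and the convergence time from the fully
#' uncommitted state. Convergence time is measured as the first sustained
#' time at which the squared distance from the (numerically computed)
#' stable fixed point falls below `tol`, matching the asymptotic-convergence
#' definition. Stronger stop signalling speeds up convergence but pushes
#' the fixed point away from the target; stronger recruitment improves
#' both.
#'
#' @param qualities,a,r Scenario parameters.
#' @param z_grid Increasing grid of stop-signal strengths (default: log
#'   spaced over an order of magnitude above the exactness point
#'   `a * rho`).
#' @param rho_grid Optional increasing grid of recruitment coefficients for
#'   the inset sweep. Because the exactness point `a * rho` sets the natural
#'   scale of the stop signal, the `rho` sweep holds the *relative*
#'   stop-signal strength fixed (`z = z_over_exact * a * rho`), isolating
#'   the effect of recruitment strength.
#' @param z_over_exact Ratio `z / (a * rho)` used along the `rho` sweep
#'   (default 15.5, the canonical scenario's ratio: `z = 3.1` at
#'   `a = 1e-3`, `rho = 200`).
#' @param tol,horizon Convergence-time settings.
#' @return List of data frames `z_sweep` (`z`, `fixed_point_r2`,
#'   `convergence_time`) and `rho_sweep` (`rho`, ...), with non-convergent
#'   grid points reported as `NA` rows rather than dropped.
#' @export
tradeoff_sweep <- function(qualities = c(0.75, 0.5, 0.25), a = 1e-3, r = 100,
                           z_grid = NULL, rho_grid = NULL, z_over_exact = 15.5,
                           tol = 1e-4, horizon = 1e7) {
  env <- make_environment(qualities)
  target <- target_distribution(env)
  rho0 <- equalise_recruitment(r, env, "negative_feedback")
  if (is.null(z_grid)) {
    z_grid <- 10^seq(log10(1.5 * exact_z(a, rho0)),
                     log10(40 * exact_z(a, rho0)), length.out = 12L)
  }
  eval_point <- function(sys) {
    fp <- tryCatch(find_fixed_point(sys), error = function(e) NULL)
    if (is.null(fp)) return(c(NA_real_, NA_real_))
    ct <- tryCatch(
      convergence_time(sys, target = fp$x, tol = tol, horizon = horizon,
                       check_fixed_point = FALSE),
      error = function(e) NA_real_)
    c(r2_error(fp$x, target), ct)
  }
  z_rows <- t(vapply(z_grid, function(z) {
    eval_point(foraging_model("negative_feedback", qualities, a = a, r = r,
                              z = z))
  }, numeric(2)))
  z_sweep <- data.frame(z = z_grid, fixed_point_r2 = z_rows[, 1],
                        convergence_time = z_rows[, 2])
  rho_sweep <- NULL
  if (!is.null(rho_grid)) {
    rho_rows <- t(vapply(rho_grid, function(rho) {
      eval_point(foraging_model("negative_feedback", qualities, a = a,
                                r = rho * mean(qualities),
                                z = z_over_exact * a * rho))
    }, numeric(2)))
    rho_sweep <- data.frame(rho = rho_grid, fixed_point_r2 = rho_rows[, 1],
                            convergence_time = rho_rows[, 2])
  }
  list(z_sweep = z_sweep, rho_sweep = rho_sweep)
}

#' Variance reduction across a parameter grid
#'
#' For every combination of population size, recruitment strength and
#' quality vector, runs paired-seed ensembles of both social variants and
#' records the per-patch stationary variance ratio
#' (negative-feedback / positive-only). The stop-signal strength scales
#' with the exactness point: `z = z_factor * a * rho` (the canonical
#' scenario corresponds to `z_factor = 15.5`).
#'
#' @param S_values,r_values Grids of population sizes and recruitment
#'   strengths.
#' @param quality_sets List of quality vectors.
#' @param a Abandonment rate.
#' @param z_factor Multiple of `exact_z(a, rho)` used for the stop signal.
#' @param n_runs Runs per variant per grid point.
#' @param t_end,t_eval Horizon and evaluation time.
#' @param master_seed Master seed (shared, paired across variants).
#' @return List with data frame `grid` (one row per grid point x patch,
#'   with both variances and their ratio) and `fraction_reduced`, the
#'   fraction of grid points where every patch has ratio < 1.
#' @export
variance_reduction_sweep <- function(S_values = c(100, 200),
                                     r_values = c(50, 100),
                                     quality_sets = list(c(0.75, 0.5, 0.25),
                                                         c(0.9, 0.6, 0.3)),
                                     a = 1e-3, z_factor = 15.5, n_runs = 100,
                                     t_end = 400, t_eval = 400,
                                     master_seed = 1) {
  rows <- list()
  point_ok <- logical(0)
  for (qi in seq_along(quality_sets)) {
    q <- quality_sets[[qi]]
    env <- make_environment(q)
    for (S in S_values) for (r in r_values) {
      rho <- equalise_recruitment(r, env, "negative_feedback")
      z <- z_factor * exact_z(a, rho)
      p <- list(qualities = q, a = a, r = r, z = z, S = S,
                t_end = t_end, t_eval = t_eval)
      cmp <- variance_comparison(p, n_runs = n_runs, master_seed = master_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        quality_set = qi, S = S, r = r, z = z, patch = seq_along(q),
        var_positive_only = cmp$positive_only$variance,
        var_negative_feedback = cmp$negative_feedback$variance,
        ratio = cmp$variance_ratio
      )
      point_ok <- c(point_ok, all(cmp$variance_ratio < 1))
    }
  }
  list(grid = do.call(rbind, rows), fraction_reduced = mean(point_ok))
}

#' Abandonment sweep: asocial negative feedback is not enough
#'
#' Raises the abandonment (leak) rate of the positive-only model across a
#' grid and compares its per-patch stationary variance against the
#' negative-feedback model at its canonical parameters, with matched `S`
#' and paired seeds. Abandonment is an independent (asocial) form of
#' negative feedback; the sweep quantifies whether increasing it can match
#' the variance suppression of social stop signalling.
#'
#' @param a_grid Grid of abandonment rates for the positive-only model.
#' @param params Canonical scenario (supplies qualities, `r`, `z`, `S`,
#'   times, and the abandonment of the negative-feedback reference).
#' @param n_runs Runs per ensemble.
#' @param master_seed Master seed.
#' @return List with data frame `grid` (per `a` x patch: positive-only
#'   variance and the negative-feedback reference variance) and
#'   `min_ratio`, the smallest (positive-only / negative-feedback) variance
#'   ratio observed across the whole grid.
#' @export
abandonment_sweep <- function(a_grid = 10^seq(-4, -2, length.out = 5),
                              params = canonical_parameters(),
                              n_runs = 100, master_seed = 1) {
  neg <- foraging_model("negative_feedback", params$qualities, a = params$a,
                        r = params$r, z = params$z)
  ref <- run_ensemble(neg, S = params$S, n_runs = n_runs,
                      t_end = params$t_end, master_seed = master_seed)
  var_ref <- ensemble_variance(ref, params$t_eval)
  rows <- lapply(a_grid, function(a) {
    pos <- foraging_model("positive_only", params$qualities, a = a,
                          r = params$r)
    e <- run_ensemble(pos, S = params$S, n_runs = n_runs,
                      t_end = params$t_end, master_seed = master_seed)
    v <- ensemble_variance(e, params$t_eval)
    data.frame(a = a, patch = seq_along(v), var_positive_only = v,
               var_negative_feedback = var_ref, ratio = v / var_ref)
  })
  grid <- do.call(rbind, rows)
  list(grid = grid, min_ratio = min(grid$ratio))
}

#' Re-convergence after an environmental change
#'
#' Integrates the mean-field dynamics of both social variants from a set of
#' initial conditions (optionally via a pre-switch phase in a first
#' environment), then measures the convergence time to the new
#' environment's stable fixed point. The spread (coefficient of variation)
#' of convergence times across initial conditions quantifies how sensitive
#' each variant is to its starting state.
#'
#' @param qualities_before,qualities_after Quality vectors before and after
#'   the switch. When `switch_time > 0` each initial condition is first
#'   evolved in the `before` environment for `switch_time` time units.
#' @param switch_time Duration of the pre-switch phase (0 = start directly
#'   from the supplied initial conditions).
#' @param n_inits Number of random initial conditions. Adaptation concerns
#'   a colony that is already deployed, so each initial state commits
#'   `1 - uncommitted_init` of the colony with a Dirichlet-uniform random
#'   allocation across patches (positive-feedback-only dynamics can only
#'   reallocate committed foragers through the slow leak, which is exactly
#'   what makes its adaptation time depend on the starting allocation).
#' @param uncommitted_init Uncommitted fraction of every initial state.
#' @param a,r,z Rates (canonical defaults).
#' @param seed Seed for drawing initial conditions.
#' @param tol,horizon Convergence settings.
#' @return List with data frame `times` (`variant`, `init_id`,
#'   `convergence_time`, `relative` = time divided by the variant's own
#'   convergence time from the fully uncommitted state), per-variant
#'   coefficients of variation `cv`, per-variant `spread`
#'   (max/min time across initial states), and `baseline_time` (the
#'   fully-uncommitted reference times). A variant adapts robustly when its
#'   `relative` values stay near 1: reaching the new target from any
#'   already-committed state costs no more than converging from scratch.
#'   Positive feedback alone can only reallocate committed foragers through
#'   the slow leak, so its `relative` values are orders of magnitude above
#'   1.
#' @export
adaptation_experiment <- function(qualities_before = c(0.75, 0.5, 0.25),
                                  qualities_after = c(0.25, 0.5, 0.75),
                                  switch_time = 0, n_inits = 10,
                                  a = 1e-3, r = 100, z = 3.1, seed = 1,
                                  uncommitted_init = 0.05,
                                  tol = 1e-4, horizon = 1e8) {
  n <- length(qualities_after)
  stopifnot(length(qualities_before) == n)
  inits <- withr::with_seed(seed, {
    lapply(seq_len(n_inits), function(i) {
      g <- rgamma(n, shape = 1)
      (1 - uncommitted_init) * g / sum(g)
    })
  })
  p_before <- list(qualities = qualities_before, a = a, r = r, z = z)
  p_after <- list(qualities = qualities_after, a = a, r = r, z = z)
  sys_before <- both_variants(p_before)
  sys_after <- both_variants(p_after)
  rows <- list()
  baseline <- numeric(0)
  for (variant in names(sys_after)) {
    fp <- find_fixed_point(sys_after[[variant]])
    baseline[variant] <- convergence_time(
      sys_after[[variant]], target = fp$x, tol = tol, horizon = horizon,
      check_fixed_point = FALSE)
    for (i in seq_len(n_inits)) {
      x0 <- inits[[i]]
      if (switch_time > 0) {
        tr <- integrate_ode(sys_before[[variant]], init = x0,
                            times = c(0, switch_time / 2, switch_time))
        x0 <- tr$x[nrow(tr$x), ]
      }
      ct <- convergence_time(sys_after[[variant]], init = x0, target = fp$x,
                             tol = tol, horizon = horizon,
                             check_fixed_point = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, init_id = i, convergence_time = ct,
        relative = ct / baseline[variant])
    }
  }
  times <- do.call(rbind, rows)
  by_var <- split(times$convergence_time, times$variant)
  cv <- vapply(by_var, function(v) {
    if (mean(v) == 0) 0 else sd(v) / mean(v)
  }, numeric(1))
  spread <- vapply(by_var, function(v) {
    if (min(v) == 0) Inf else max(v) / min(v)
  }, numeric(1))
  list(times = times, cv = cv, spread = spread, baseline_time = baseline)
}

#' Asocial baseline: discovery and abandonment only
#'
#' The ancestral foraging mode without any social feedback: individuals
#' discover patches independently (at rate `q_i`) and abandon them (at
#' rate `a`). The fixed point is `x_i = q_i x_U / a` with
#' `x_U = a / (a + sum q_j)` — committed fractions exactly proportional to
#' quality, but with a large uncommitted residual and convergence on the
#' slow `1/a` timescale. Optionally also runs an SSA ensemble for the
#' stationary variance.
#'
#' @param qualities Patch qualities.
#' @param a Abandonment rate.
#' @param S,n_runs,t_end,t_eval,master_seed SSA ensemble settings (skipped
#'   when `n_runs = 0`).
#' @param tol,horizon Convergence-time settings.
#' @return List with `fixed_point` (a `stability_report`),
#'   `convergence_time` (from the fully uncommitted start, which stays
#'   exactly proportional and is therefore fast), `timescale` (the slow
#'   relaxation timescale `1 / |Re lambda_max|`; the asocial Jacobian has
#'   eigenvalue `-a` with multiplicity `n - 1`, so generic perturbations
#'   decay on the long `1/a` timescale), and when requested `variance`
#'   (per patch).
#' @export
asocial_baseline <- function(qualities = c(0.75, 0.5, 0.25), a = 1e-3,
                             S = 200, n_runs = 0, t_end = 10 / a,
                             t_eval = 10 / a, master_seed = 1,
                             tol = 1e-4, horizon = 1e7) {
  sys <- foraging_model("asocial", qualities, a = a)
  fp <- find_fixed_point(sys)
  ct <- convergence_time(sys, target = fp$x, tol = tol, horizon = horizon,
                         check_fixed_point = FALSE)
  out <- list(fixed_point = fp, convergence_time = ct,
              timescale = 1 / abs(max(Re(fp$eigenvalues))))
  if (n_runs > 0) {
    e <- run_ensemble(sys, S = S, n_runs = n_runs, t_end = t_end,
                      master_seed = master_seed)
    out$variance <- ensemble_variance(e, t_eval)
  }
  out
}

#' Probability of a large deviation from the target
#'
#' Empirical probability, per variant, that a run's squared distance from
#' the target at `t_eval` exceeds a threshold `delta`, with exact binomial
#' confidence intervals.
#'
#' @param params Scenario list (see [canonical_parameters()]).
#' @param delta Threshold on the squared distance.
#' @param n_runs Runs per variant.
#' @param master_seed Master seed (paired across variants).
#' @param conf_level Confidence level for the binomial interval.
#' @return Data frame with one row per variant: `exceedances`, `n_runs`,
#'   `probability`, `ci_low`, `ci_high`.
#' @export
deviation_probability <- function(params = canonical_parameters(),
                                  delta, n_runs = 200, master_seed = 1,
                                  conf_level = 0.95) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta >= 0)
  systems <- both_variants(params)
  target <- target_distribution(systems[[1]]$environment)
  rows <- lapply(names(systems), function(variant) {
    e <- run_ensemble(systems[[variant]], S = params$S, n_runs = n_runs,
                      t_end = params$t_end, master_seed = master_seed)
    s <- ensemble_sse(e, target, params$t_eval)
    k <- sum(s > delta)
    ci <- binom.test(k, n_runs, conf.level = conf_level)$conf.int
    data.frame(variant = variant, exceedances = k, n_runs = n_runs,
               probability = k / n_runs, ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, rows)
}
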