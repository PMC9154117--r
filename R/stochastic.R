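#' Reaction propensities of a count state
#'
#' Stochastic rate of each reaction channel at integer counts `X` for a
#' population of size `S = sum(X)`. Discovery fires at `q_i X_U`,
#' abandonment at `a X_i`, recruitment at `(r_i / S) X_U X_i`, and stop
#' signalling at `(z / S) X_i (X_i - 1)` (an ordered pair of distinct
#' individuals on the same patch, without a symmetry factor). This scaling
#' reproduces the mean-field terms `r_i x_U x_i` and `z x_i^2` exactly in
#' the infinite-population limit, which keeps the two engines mutually
#' consistent. Channels with no available reactants have propensity exactly
#' zero.
#'
#' @param counts Integer vector of `n + 1` counts (`U` first, then patches).
#' @param system A `reaction_system`.
#' @return Numeric vector of propensities, one per reaction (row order of
#'   `system$reactions`).
#' @export
propensities <- function(counts, system) {
  stopifnot(inherits(system, "reaction_system"))
  n <- system$environment$n
  check_count_state(counts, n)
  S <- sum(counts)
  rx <- system$reactions
  vapply(seq_len(nrow(rx)), function(k) {
    i <- rx$r1[k]; j <- rx$r2[k]
    if (is.na(j)) rx$rate[k] * counts[i]
    else if (j == i) rx$rate[k] / S * counts[i] * (counts[i] - 1)
    else rx$rate[k] / S * counts[i] * counts[j]
  }, numeric(1))
}

check_count_state <- function(counts, n) {
  if (length(counts) != n + 1L) {
    stop(sprintf("count state must have %d entries (U first, then %d patches)",
                 n + 1L, n), call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(TRUE)
}

#' Single exact stochastic simulation run
#'
#' Gillespie direct-method simulation of a finite population of `S`
#' foragers. The run is reproducible: the same `(system, init, seed)`
#' produces the identical event sequence. States are recorded on a fixed
#' time grid (left-hold, right-continuous at event times); the full event
#' log can optionally be kept for audits.
#'
#' @param system A `reaction_system`.
#' @param S Population size (`>= 2`). Ignored when `init` is given.
#' @param t_end Simulation horizon, `> 0`.
#' @param seed Integer seed for this run.
#' @param init Optional integer vector of `n + 1` initial counts summing to
#'   the population size; the default places all `S` individuals in the
#'   uncommitted state.
#' @param record_times Time grid on which states are recorded (default 401
#'   evenly spaced points over `[0, t_end]`).
#' @param record_events Keep the full event log (times plus source and
#'   destination species of every jump)?
#' @param max_events Optional cap on the number of events simulated.
#' @return An object of class `ssa_trajectory`: list with `times`, integer
#'   matrix `counts` (rows = grid times, columns = species `U, patch_1,
#'   ...`), `S`, `seed`, `t_end`, `n_events`, `absorbed`, and when requested
#'   `events` (data frame `time`, `from`, `to`).
#' @export
gillespie_run <- function(system, S = NULL, t_end, seed, init = NULL,
                          record_times = NULL, record_events = FALSE,
                          max_events = Inf) {
  stopifnot(inherits(system, "reaction_system"))
  n <- system$environment$n
  if (is.null(init)) {
    if (is.null(S) || S < 2) stop("'S' must be at least 2", call. = FALSE)
    init <- c(as.integer(S), integer(n))
  } else {
    check_count_state(init, n)
    init <- as.integer(round(init))
    if (!is.null(S) && sum(init) != S) {
      stop("'init' must sum to 'S'", call. = FALSE)
    }
    S <- sum(init)
  }
  if (t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  if (is.null(record_times)) {
    record_times <- seq(0, t_end, length.out = 401L)
  }
  if (any(record_times < 0) || any(record_times > t_end) ||
      is.unsorted(record_times)) {
    stop("'record_times' must be sorted within [0, t_end]", call. = FALSE)
  }
  rx <- system$reactions

  raw <- withr::with_seed(as.integer(seed),
    ssa_run_cpp(init,
                as.integer(rx$r1 - 1L),
                as.integer(ifelse(is.na(rx$r2), 0L, rx$r2) - 1L),
                as.integer(rx$src - 1L),
                as.integer(rx$dst - 1L),
                as.numeric(rx$rate),
                t_end, as.numeric(record_times),
                record_events, max_events))

  counts <- raw$counts
  colnames(counts) <- species_names(n)
  out <- list(times = record_times, counts = counts, S = S,
              seed = as.integer(seed), t_end = t_end,
              n_events = raw$n_events, absorbed = raw$absorbed,
              system = system)
  if (record_events) {
    out$events <- data.frame(time = raw$event_times,
                             from = raw$event_src + 1L,
                             to = raw$event_dst + 1L)
  }
  structure(out, class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("SSA trajectory: S =", x$S, ", t_end =", x$t_end,
      ", events =", format(x$n_events, big.mark = ","),
      ", seed =", x$seed, "\n")
  fin <- x$counts[nrow(x$counts), ]
  cat("  final counts:", paste(fin, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ssa_trajectory <- function(x, ...) {
  n <- ncol(x$counts) - 1L
  sp <- species_names(n)
  data.frame(
    time = rep(x$times, n + 1L),
    species = rep(sp, each = length(x$times)),
    count = as.vector(x$counts),
    fraction = as.vector(x$counts) / x$S
  )
}

#' State of a run at an arbitrary time
#'
#' Left-hold sampling: returns the state after the last recorded change at
#' or before `t` (right-continuous at event times). Uses the event log when
#' present, otherwise the recording grid.
#'
#' @param trajectory An `ssa_trajectory`.
#' @param t Time in `[0, t_end]`.
#' @return Integer vector of `n + 1` counts.
#' @export
state_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "ssa_trajectory"))
  if (t < 0 || t > trajectory$t_end) {
    stop("'t' must lie within the simulated horizon [0, t_end]", call. = FALSE)
  }
  if (!is.null(trajectory$events)) {
    x <- trajectory$counts[1L, ]
    ev <- trajectory$events
    keep <- ev$time <= t
    if (any(keep)) {
      x <- x - tabulate(ev$from[keep], nbins = length(x)) +
        tabulate(ev$to[keep], nbins = length(x))
    }
    return(as.integer(x))
  }
  idx <- findInterval(t, trajectory$times)
  as.integer(trajectory$counts[max(idx, 1L), ])
}

#' Run an ensemble of independent SSA realisations
#'
#' Runs `n_runs` mutually independent Gillespie simulations with per-run
#' seeds derived deterministically from the master seed
#' (`seed_k = master_seed + k - 1`, recorded in the output so every run is
#' auditable). The same configuration and master seed always reproduce the
#' identical ensemble. Because the seed stream depends only on
#' `(master_seed, k)`, paired comparisons between model variants can reuse
#' one master seed to share randomness run-for-run.
#'
#' @inheritParams gillespie_run
#' @param n_runs Number of independent runs (`>= 1`).
#' @param master_seed Integer master seed.
#' @return An object of class `ssa_ensemble`: list with `times`, 3-d integer
#'   array `counts` (time x species x run), `seeds`, `S`, `t_end` and the
#'   `system`.
#' @export
run_ensemble <- function(system, S, n_runs, t_end, master_seed,
                         init = NULL, record_times = NULL) {
  stopifnot(inherits(system, "reaction_system"))
  if (n_runs < 1) stop("'n_runs' must be at least 1", call. = FALSE)
  if (is.null(record_times)) record_times <- seq(0, t_end, length.out = 401L)
  seeds <- (as.integer(master_seed) + seq_len(n_runs) - 1L) %% .Machine$integer.max
  n <- system$environment$n
  counts <- array(0L, dim = c(length(record_times), n + 1L, n_runs),
                  dimnames = list(NULL, species_names(n), NULL))
  for (k in seq_len(n_runs)) {
    run <- gillespie_run(system, S = S, t_end = t_end, seed = seeds[k],
                         init = init, record_times = record_times)
    counts[, , k] <- run$counts
  }
  structure(
    list(times = record_times, counts = counts, seeds = seeds, S = S,
         t_end = t_end, n_runs = n_runs, master_seed = as.integer(master_seed),
         system = system),
    class = "ssa_ensemble"
  )
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat("SSA ensemble:", x$n_runs, "runs, S =", x$S, ", t_end =", x$t_end,
      ", master seed =", x$master_seed, "\n")
  invisible(x)
}

#' Committed fractions of every run at a time point
#'
#' @param ensemble An `ssa_ensemble`.
#' @param t_eval Evaluation time (snapped to the last recorded grid time at
#'   or before `t_eval`).
#' @return Numeric matrix, runs in rows, patches in columns.
#' @export
ensemble_fractions <- function(ensemble, t_eval) {
  stopifnot(inherits(ensemble, "ssa_ensemble"))
  if (t_eval < 0 || t_eval > ensemble$t_end + 1e-9) {
    stop("'t_eval' outside the simulated horizon", call. = FALSE)
  }
  idx <- max(findInterval(t_eval + 1e-9, ensemble$times), 1L)
  n <- dim(ensemble$counts)[2L] - 1L
  fr <- vapply(seq_len(ensemble$n_runs),
               function(k) as.numeric(ensemble$counts[idx, -1L, k]),
               numeric(n))
  fr <- t(matrix(fr, nrow = n)) / ensemble$S
  colnames(fr) <- species_names(n)[-1L]
  fr
}

#' @export
as.data.frame.ssa_ensemble <- function(x, ...) {
  n <- dim(x$counts)[2L] - 1L
  sp <- species_names(n)
  nt <- length(x$times)
  do.call(rbind, lapply(seq_len(x$n_runs), function(k) {
    data.frame(
      run_id = k,
      time = rep(x$times, n + 1L),
      species = rep(sp, each = nt),
      count = as.vector(x$counts[, , k]),
      fraction = as.vector(x$counts[, , k]) / x$S
    )
  }))
}
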