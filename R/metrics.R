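#' Squared distance from a target allocation
#'
#' `R^2 = sum_i (x_i - x_i*)^2` over committed fractions; the uncommitted
#' fraction is excluded because the target is defined over forage patches
#' only.
#'
#' @param committed Numeric vector of `n` committed fractions.
#' @param target Numeric vector of `n` target fractions.
#' @return Non-negative scalar.
#' @examples
#' r2_error(c(0.6, 0.4), c(0.5, 0.5))  # 0.02
#' @export
r2_error <- function(committed, target) {
  if (length(committed) != length(target)) {
    stop("'committed' and 'target' must have the same length", call. = FALSE)
  }
  sum((committed - target)^2)
}

#' Per-run sum of squared errors at an evaluation time
#'
#' For each run of an ensemble, the squared distance of the committed
#' fractions (`counts / S`) from the target at `t_eval`. This is the per-run
#' [r2_error()] evaluated at a fixed late time; fractions (not raw counts)
#' are used so values are comparable across population sizes. The full
#' distribution is returned for boxplotting.
#'
#' @param ensemble An `ssa_ensemble`.
#' @param target Numeric vector of `n` target fractions.
#' @param t_eval Evaluation time within the simulated horizon.
#' @return Numeric vector, one SSE per run.
#' @export
ensemble_sse <- function(ensemble, target, t_eval) {
  stopifnot(inherits(ensemble, "ssa_ensemble"))
  if (ensemble$n_runs < 1) stop("empty ensemble", call. = FALSE)
  fr <- ensemble_fractions(ensemble, t_eval)
  if (ncol(fr) != length(target)) {
    stop("'target' length does not match the number of patches", call. = FALSE)
  }
  colSums((t(fr) - target)^2)
}

#' Per-patch ensemble variance of committed fractions
#'
#' Unbiased sample variance (divisor `n_runs - 1`) across runs, per patch,
#' of the committed fractions at `t_eval`.
#'
#' @inheritParams ensemble_sse
#' @return Numeric vector of `n` variances.
#' @export
ensemble_variance <- function(ensemble, t_eval) {
  stopifnot(inherits(ensemble, "ssa_ensemble"))
  if (ensemble$n_runs < 2) {
    stop("variance needs at least 2 runs", call. = FALSE)
  }
  fr <- ensemble_fractions(ensemble, t_eval)
  apply(fr, 2L, var)
}

#' Convergence delay in orders of magnitude
#'
#' `log10(t_slow / t_fast)`: how many orders of magnitude slower one
#' convergence is than another.
#'
#' @param t_slow,t_fast Positive convergence times.
#' @return Scalar (positive when `t_slow > t_fast`).
#' @export
delay_log10 <- function(t_slow, t_fast) {
  if (t_slow <= 0 || t_fast <= 0) {
    stop("both times must be positive", call. = FALSE)
  }
  log10(t_slow / t_fast)
}

#' Tukey boxplot summary
#'
#' Median, quartiles, whiskers at 1.5 IQR, and outliers — the conventional
#' five-number boxplot statistics.
#'
#' @param x Numeric vector.
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
tukey_stats <- function(x) {
  fn <- stats::fivenum(x)       # Tukey hinges, as in classical boxplots
  qs <- fn[2:4]
  iqr <- qs[3] - qs[1]
  lo <- qs[1] - 1.5 * iqr
  hi <- qs[3] + 1.5 * iqr
  inside <- x[x >= lo & x <= hi]
  list(median = qs[2], q1 = qs[1], q3 = qs[3],
       whisker_low = if (length(inside)) min(inside) else NA_real_,
       whisker_high = if (length(inside)) max(inside) else NA_real_,
       outliers = sort(x[x < lo | x > hi]))
}

#' Proportionality error of the committed allocation
#'
#' Squared distance between the committed allocation renormalised to its
#' own sum (`x_i / sum_j x_j`) and a target distribution. This isolates how
#' the colony *shares* its committed foragers across patches from how many
#' foragers remain uncommitted: a fixed point whose committed fractions are
#' exactly proportional to the qualities scores 0 even though a small
#' uncommitted residual keeps the raw [r2_error()] positive.
#'
#' @param committed Numeric vector of `n` committed fractions with positive
#'   sum.
#' @param target Numeric vector of `n` target fractions.
#' @return Non-negative scalar; 0 iff `committed` is proportional to
#'   `target`.
#' @export
allocation_r2 <- function(committed, target) {
  if (length(committed) != length(target)) {
    stop("'committed' and 'target' must have the same length", call. = FALSE)
  }
  s <- sum(committed)
  if (s <= 0) stop("'committed' must have a positive sum", call. = FALSE)
  sum((committed / s - target)^2)
}
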