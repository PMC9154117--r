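#' Equalise recruitment strength between model variants
#'
#' Derives the recruitment coefficient `rho` so that recruitment happens on
#' average at the same rate `r` in every social variant: the positive-only
#' model uses quality-insensitive recruitment, so `rho = r`; the
#' negative-feedback model uses quality-sensitive recruitment `r_i = rho
#' q_i`, so `rho = r / mean(q)` (unweighted arithmetic mean over patches),
#' making the patch-averaged rate `mean(rho q_i)` equal to `r`. The asocial
#' baseline has no recruitment (`rho = 0`).
#'
#' @param r Average recruitment strength, `> 0` for social variants.
#' @param env A [make_environment()] object.
#' @param variant Model variant tag.
#' @return The recruitment coefficient `rho`.
#' @examples
#' env <- make_environment(c(0.75, 0.5, 0.25))
#' equalise_recruitment(100, env, "negative_feedback")  # 200
#' @export
equalise_recruitment <- function(r, env, variant) {
  variant <- match.arg(variant, .variants)
  stopifnot(inherits(env, "patch_environment"))
  if (variant == "asocial") return(0)
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0) {
    stop("'r' must be a single positive number", call. = FALSE)
  }
  switch(variant,
    positive_only = r,
    negative_feedback = r / mean(env$qualities)
  )
}

#' Stop-signal strength giving an exactly proportional fixed point
#'
#' For the negative-feedback model, the stop-signal strength `z = a * rho`
#' makes the mean-field fixed point land exactly on the quality-proportional
#' target: substituting `x_i = c q_i` with `x_U = a c` into the rate
#' equations `q_i x_U - a x_i + rho q_i x_U x_i - z x_i^2` leaves
#' `c^2 q_i^2 (a rho - z)`, which vanishes for every patch precisely at
#' `z = a rho` (and conservation then fixes `c = 1 / (a + sum q_j)`).
#'
#' @param a Abandonment rate (`>= 0`).
#' @param rho Recruitment coefficient (`>= 0`).
#' @return The exactness point `z = a * rho` (0 when `a = 0`: with no leak,
#'   no inhibition is needed).
#' @export
exact_z <- function(a, rho) {
  if (a < 0 || rho < 0) stop("'a' and 'rho' must be non-negative", call. = FALSE)
  a * rho
}

#' Tune the stop-signal strength numerically
#'
#' One-dimensional deterministic optimisation of the stop-signal strength
#' `z` for the negative-feedback model. With `objective = "min_error"` the
#' fixed-point proportionality error ([allocation_r2()], which is exactly 0
#' when the committed allocation matches the target shares) is minimised by
#' golden-section search on `log z`; this recovers the closed form
#' [exact_z()] and serves as its self-test. With
#' `objective = "error_speed_tradeoff"` the weighted objective
#' `R^2(z) + lambda * T(z)` is minimised over a log-spaced `z` grid with
#' local golden-section refinement, where `T(z)` is the convergence time
#' from the fully uncommitted state; `lambda = 0` reduces to the pure error
#' objective. No randomness is involved, so results are reproducible
#' without seeds.
#'
#' @param env A [make_environment()] object.
#' @param a Abandonment rate.
#' @param r Average recruitment strength (equalised, so `rho = r / mean(q)`).
#' @param objective `"min_error"` or `"error_speed_tradeoff"`.
#' @param lambda Non-negative weight on convergence time in the trade-off
#'   objective (units: 1 / time).
#' @param z_range Search interval for `z` (default spans four orders of
#'   magnitude around `exact_z`).
#' @param grid_points Grid size for the trade-off search.
#' @param conv_tol,horizon Convergence-time settings (see
#'   [convergence_time()]).
#' @return An object of class `parameterisation_result`: list with `rates`
#'   (a [rate_parameters()] object at the optimal `z`), `z`, `achieved_r2`
#'   (fixed-point proportionality error), `convergence_time`
#'   (`NA` for pure `min_error`), and `notes` recording the provenance of
#'   each chosen value.
#' @export
optimise_z <- function(env, a, r,
                       objective = c("min_error", "error_speed_tradeoff"),
                       lambda = 0, z_range = NULL, grid_points = 21L,
                       conv_tol = 1e-4, horizon = 1e7) {
  objective <- match.arg(objective)
  stopifnot(inherits(env, "patch_environment"), a > 0, r > 0, lambda >= 0)
  rho <- equalise_recruitment(r, env, "negative_feedback")
  z0 <- exact_z(a, rho)
  if (is.null(z_range)) z_range <- c(z0 / 100, z0 * 100)
  if (z_range[1] <= 0 || z_range[2] <= z_range[1]) {
    stop("'z_range' must be an increasing positive interval", call. = FALSE)
  }
  target <- target_distribution(env)
  fp_r2 <- function(z) {
    sys <- foraging_model("negative_feedback", env$qualities, a = a, r = r, z = z)
    allocation_r2(find_fixed_point(sys)$x, target)
  }

  if (objective == "min_error" || lambda == 0) {
    opt <- optimize(function(lz) fp_r2(exp(lz)), interval = log(z_range),
                    tol = 1e-10)
    z_star <- exp(opt$minimum)
    ct <- NA_real_
    note <- "z from golden-section minimisation of fixed-point R^2 on log z"
  } else {
    conv_t <- function(z) {
      sys <- foraging_model("negative_feedback", env$qualities,
                            a = a, r = r, z = z)
      fp <- find_fixed_point(sys)
      convergence_time(sys, target = fp$x, tol = conv_tol, horizon = horizon,
                       check_fixed_point = FALSE)
    }
    obj <- function(z) fp_r2(z) + lambda * conv_t(z)
    zg <- exp(seq(log(z_range[1]), log(z_range[2]), length.out = grid_points))
    vals <- vapply(zg, obj, numeric(1))
    k <- which.min(vals)
    lo <- zg[max(k - 1L, 1L)]
    hi <- zg[min(k + 1L, length(zg))]
    if (lo == hi) stop("failed to bracket a minimum in 'z_range'", call. = FALSE)
    opt <- optimize(function(lz) obj(exp(lz)), interval = log(c(lo, hi)),
                    tol = 1e-6)
    z_star <- exp(opt$minimum)
    ct <- conv_t(z_star)
    note <- sprintf(
      "z from log-spaced grid (%d points) + golden-section refinement of R^2 + %g * T",
      grid_points, lambda)
  }

  rates <- rate_parameters(env, "negative_feedback", a = a, r = r, z = z_star)
  structure(
    list(rates = rates, z = z_star, achieved_r2 = fp_r2(z_star),
         convergence_time = ct,
         notes = c(rho = "equalised: rho = r / mean(q)", z = note)),
    class = "parameterisation_result"
  )
}

#' @export
print.parameterisation_result <- function(x, ...) {
  cat("Parameterisation result: z =", signif(x$z, 8),
      ", fixed-point R^2 =", format(x$achieved_r2, digits = 4), "\n")
  if (is.finite(x$convergence_time)) {
    cat("  convergence time:", signif(x$convergence_time, 6), "\n")
  }
  for (nm in names(x$notes)) cat("  ", nm, ": ", x$notes[[nm]], "\n", sep = "")
  invisible(x)
}

#' Serialise a parameterisation result to JSON
#'
#' @param x A `parameterisation_result`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
parameterisation_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "parameterisation_result"))
  obj <- list(
    variant = x$rates$variant,
    a = x$rates$a, r = x$rates$r, rho = x$rates$rho, z = x$z,
    r_i = x$rates$r_i,
    achieved_r2 = x$achieved_r2,
    convergence_time = x$convergence_time,
    provenance = as.list(x$notes)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Rank rate-function families by achievable accuracy
#'
#' Compares candidate recruitment-rate families (`constant`: `r_i = rho`;
#' `linear_in_quality`: `r_i = rho q_i`) with and without a constant
#' stop-signal channel, at matched average recruitment strength `r`. Each
#' combination is parameterised by [equalise_recruitment()], its mean-field
#' fixed point is computed, and candidates are ranked by squared distance
#' from the quality-proportional target. Without negative feedback the
#' constant recruitment function is exact; once a stop-signal channel is
#' present the recruitment function must switch to linear in quality to
#' stay accurate.
#'
#' @param env A [make_environment()] object.
#' @param a Abandonment rate.
#' @param r Average recruitment strength.
#' @param z Stop-signal strength used by the with-negative-feedback
#'   candidates (default: the canonical exactness point `a * rho` of the
#'   linear family).
#' @param families Character vector of recruitment families to consider.
#' @return Data frame with one row per (recruitment family, stop-signal)
#'   combination: `recruitment`, `stop_signal`, `z`, `rho`,
#'   `fixed_point_r2`, and `rank` within each stop-signal group (1 = best).
#' @export
rate_function_search <- function(env, a, r, z = NULL,
                                 families = c("constant", "linear_in_quality")) {
  stopifnot(inherits(env, "patch_environment"), a > 0, r > 0)
  if (length(families) == 0) stop("empty candidate set", call. = FALSE)
  families <- match.arg(families, c("constant", "linear_in_quality"),
                        several.ok = TRUE)
  q <- env$qualities
  target <- target_distribution(env)
  if (is.null(z)) z <- exact_z(a, r / mean(q))

  eval_combo <- function(recruitment, with_stop) {
    rho <- if (recruitment == "constant") r else r / mean(q)
    r_i <- if (recruitment == "constant") rep(rho, env$n) else rho * q
    # assemble directly so mixed combinations (e.g. constant recruitment
    # with a stop signal) can be scored outside the two shipped variants
    sys <- build_generalised(env, a, r_i, if (with_stop) z else 0, rho, r)
    fp <- tryCatch(find_fixed_point(sys), error = function(e) NULL)
    if (is.null(fp)) return(NA_real_)
    r2_error(fp$x, target)
  }

  grid <- expand.grid(recruitment = families, stop_signal = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  grid$z <- ifelse(grid$stop_signal, z, 0)
  grid$rho <- ifelse(grid$recruitment == "constant", r, r / mean(q))
  grid$fixed_point_r2 <- mapply(eval_combo, grid$recruitment, grid$stop_signal)
  grid$rank <- ave(grid$fixed_point_r2, grid$stop_signal,
                   FUN = function(v) rank(v, ties.method = "min"))
  grid[order(grid$stop_signal, grid$rank), ]
}

# Internal: a reaction system with an arbitrary per-patch recruitment vector
# (used only by the rate-function search; the shipped variants remain the
# three canonical models).
build_generalised <- function(env, a, r_i, z, rho, r) {
  if (z > 0) {
    sys <- foraging_model("negative_feedback", env$qualities, a = a, r = r,
                          z = z, rho = rho)
  } else {
    sys <- foraging_model("positive_only", env$qualities, a = a, r = r,
                          rho = rho)
  }
  rec <- sys$reactions$type == "recruitment"
  sys$reactions$rate[rec] <- r_i[sys$reactions$patch[rec]]
  sys$rates$r_i <- r_i
  # closed forms in find_fixed_point assume the canonical rate functions;
  # force the numerical route when the recruitment vector was overridden
  if (sys$variant == "positive_only" && !all(r_i == rho)) {
    sys$variant <- "negative_feedback"
    sys$reactions <- rbind(
      sys$reactions,
      data.frame(type = "stop_signal", patch = seq_len(env$n), rate = 0,
                 r1 = 1L + seq_len(env$n), r2 = 1L + seq_len(env$n),
                 src = 1L + seq_len(env$n), dst = 1L)
    )
    sys$stoich <- rbind(
      sys$stoich,
      t(vapply(seq_len(env$n), function(i) {
        v <- numeric(env$n + 1L); v[1L] <- 1; v[1L + i] <- -1; v
      }, numeric(env$n + 1L)))
    )
  }
  sys
}
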