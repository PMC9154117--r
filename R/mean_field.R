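#' Mean-field right-hand side
#'
#' Time derivatives of the committed fractions in the infinite-population
#' limit, assembled generically from the compiled reaction table by
#' mass-action kinetics: each unary channel contributes `rate * x_reactant`,
#' each bimolecular channel `rate * x_r1 * x_r2` (so the same-species
#' stop-signal channel contributes `z * x_i^2`). For the three model
#' variants this evaluates to
#' `dx_i/dt = q_i x_U - a x_i + r_i x_U x_i - z x_i^2` with
#' `x_U = 1 - sum_j x_j`. The uncommitted derivative is implied by
#' conservation and not returned.
#'
#' @param x Numeric vector of `n` committed fractions.
#' @param system A `reaction_system`.
#' @return Numeric vector of `n` derivatives `dx_i/dt`.
#' @export
ode_rhs <- function(x, system) {
  stopifnot(inherits(system, "reaction_system"))
  n <- system$environment$n
  if (length(x) != n) {
    stop(sprintf("state must have %d committed fractions", n), call. = FALSE)
  }
  rx <- system$reactions
  xfull <- c(1 - sum(x), x)
  x2 <- ifelse(is.na(rx$r2), 1, xfull[ifelse(is.na(rx$r2), 1L, rx$r2)])
  flux <- rx$rate * xfull[rx$r1] * x2
  dx_full <- drop(crossprod(system$stoich, flux))
  unname(dx_full[-1L])
}

#' Analytic Jacobian of the mean-field system
#'
#' Jacobian of [ode_rhs()] in the `n` committed coordinates, with the
#' uncommitted fraction eliminated by conservation
#' (`d x_U / d x_j = -1`). Assembled by analytic differentiation of the
#' mass-action fluxes, not finite differences.
#'
#' @inheritParams ode_rhs
#' @return `n x n` numeric matrix `J[i, j] = d(dx_i/dt) / d x_j`.
#' @export
ode_jacobian <- function(x, system) {
  stopifnot(inherits(system, "reaction_system"))
  n <- system$environment$n
  rx <- system$reactions
  nfull <- n + 1L
  xfull <- c(1 - sum(x), x)
  # dflux[k, s]: derivative of flux k w.r.t. full species fraction s
  dflux <- matrix(0, nrow(rx), nfull)
  for (k in seq_len(nrow(rx))) {
    i <- rx$r1[k]; j <- rx$r2[k]
    if (is.na(j)) {
      dflux[k, i] <- rx$rate[k]
    } else if (i == j) {
      dflux[k, i] <- 2 * rx$rate[k] * xfull[i]
    } else {
      dflux[k, i] <- rx$rate[k] * xfull[j]
      dflux[k, j] <- dflux[k, j] + rx$rate[k] * xfull[i]
    }
  }
  J_full <- crossprod(system$stoich, dflux)  # nfull x nfull
  # chain rule for the conservation constraint: x_U = 1 - sum x
  J <- J_full[-1L, -1L, drop = FALSE] - J_full[-1L, 1L]
  unname(J)
}

default_init <- function(system) rep(0, system$environment$n)

#' Integrate the mean-field ODE
#'
#' Solves the infinite-population dynamics with a stiff-capable adaptive
#' integrator (`deSolve::lsoda`) using the analytic Jacobian. The default
#' tolerances are tight because the models mix rates spanning about five
#' orders of magnitude (abandonment `a ~ 1e-3` against recruitment
#' `rho q ~ 1e2`), and slow near-critical transients must be resolved
#' faithfully.
#'
#' @param system A `reaction_system`.
#' @param init Numeric vector of `n` initial committed fractions (default:
#'   fully uncommitted colony, all zeros).
#' @param t_end Final time (model time units), `> 0`. Ignored when `times`
#'   is given.
#' @param times Optional explicit output time grid (first entry may be 0).
#' @param rel_tol,abs_tol Relative and absolute integration tolerances.
#' @return An object of class `mf_trajectory`: list with `times`, matrix `x`
#'   (rows = times, columns = patches), vector `x_U`, and the `system`.
#' @export
integrate_ode <- function(system, init = NULL, t_end = NULL, times = NULL,
                          rel_tol = 1e-10, abs_tol = 1e-12) {
  stopifnot(inherits(system, "reaction_system"))
  n <- system$environment$n
  if (is.null(init)) init <- default_init(system)
  check_mf_state(init, n)
  if (is.null(times)) {
    if (is.null(t_end) || t_end <= 0) {
      stop("'t_end' must be positive when 'times' is not supplied",
           call. = FALSE)
    }
    times <- seq(0, t_end, length.out = 401L)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (rel_tol <= 0 || abs_tol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }

  fn <- function(t, y, parms) list(ode_rhs(y, system))
  jac <- function(t, y, parms) ode_jacobian(y, system)
  out <- deSolve::lsoda(y = init, times = times, func = fn, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rel_tol, atol = abs_tol, maxsteps = 50000L)
  istate <- attr(out, "istate")[1L]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times)) {
    stop("ODE integration failed (solver status ", istate,
         "); try tighter tolerances or a shorter horizon", call. = FALSE)
  }
  x <- unname(out[, -1L, drop = FALSE])
  x_U <- 1 - rowSums(x)
  if (min(x, x_U) < -1e-9) {
    stop("integration produced fractions below -1e-9; re-run with tighter ",
         "tolerances", call. = FALSE)
  }
  structure(
    list(times = unname(out[, 1L]), x = x, x_U = x_U, system = system),
    class = "mf_trajectory"
  )
}

check_mf_state <- function(x, n, tol = 1e-9) {
  if (!is.numeric(x) || length(x) != n) {
    stop(sprintf("state must be a numeric vector of %d committed fractions", n),
         call. = FALSE)
  }
  if (any(x < -tol) || sum(x) > 1 + tol) {
    stop("committed fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.mf_trajectory <- function(x, ...) {
  cat("Mean-field trajectory:", length(x$times), "time points over [",
      min(x$times), ",", max(x$times), "],", ncol(x$x), "patches\n")
  fin <- x$x[nrow(x$x), ]
  cat("  final committed fractions:",
      paste(signif(fin, 6), collapse = ", "),
      " (x_U =", signif(x$x_U[length(x$x_U)], 6), ")\n")
  invisible(x)
}

#' @export
as.data.frame.mf_trajectory <- function(x, ...) {
  n <- ncol(x$x)
  sp <- species_names(n)
  data.frame(
    time = rep(x$times, n + 1L),
    species = rep(sp, each = length(x$times)),
    fraction = c(x$x_U, as.vector(x$x))
  )
}

#' Fixed point and stability of the mean-field system
#'
#' Finds the interior fixed point of the committed dynamics and classifies
#' its stability via the analytic Jacobian spectrum. Closed forms are used
#' where they exist: for the positive-only variant
#' `x_i = q_i u / (a - rho u)` with `u = x_U` the smaller positive root of
#' `rho u^2 - (rho + a + Q) u + a = 0` (`Q = sum q_j`); for the asocial
#' variant `x_U = a / (a + Q)`, `x_i = q_i x_U / a`. For the
#' negative-feedback variant the fixed point is located by long-time
#' integration followed by Newton refinement with the analytic Jacobian.
#' All routes are polished to residual `max |dx_i/dt| < 1e-12`.
#'
#' @param system A `reaction_system`.
#' @param init_guess Optional starting committed state for the numerical
#'   route.
#' @return An object of class `stability_report`: list with `x` (committed
#'   fractions), `x_U`, `residual`, `eigenvalues` (Jacobian spectrum in the
#'   committed coordinates), and logical `stable` (all real parts negative).
#' @export
find_fixed_point <- function(system, init_guess = NULL) {
  stopifnot(inherits(system, "reaction_system"))
  n <- system$environment$n
  q <- system$environment$qualities
  a <- system$rates$a
  rho <- system$rates$rho
  Q <- sum(q)

  x0 <- switch(system$variant,
    asocial = {
      if (a <= 0) {
        stop("asocial model with a = 0 has no unique interior fixed point",
             call. = FALSE)
      }
      q * (a / (a + Q)) / a
    },
    positive_only = {
      if (rho <= 0) {
        stop("positive-only model requires rho > 0", call. = FALSE)
      }
      b <- rho + a + Q
      disc <- b^2 - 4 * rho * a
      u <- (b - sqrt(disc)) / (2 * rho)
      q * u / (a - rho * u)
    },
    negative_feedback = {
      if (is.null(init_guess)) {
        horizon <- max(100, 20 / max(a, 1e-6))
        tr <- integrate_ode(system, t_end = horizon,
                            times = c(0, horizon / 2, horizon))
        tr$x[nrow(tr$x), ]
      } else {
        init_guess
      }
    }
  )

  x <- newton_polish(x0, system)
  res <- max(abs(ode_rhs(x, system)))
  if (!is.finite(res) || res > 1e-12) {
    stop(sprintf("fixed-point residual %.3g exceeds 1e-12", res), call. = FALSE)
  }
  x_U <- 1 - sum(x)
  if (any(x <= 0) || x_U <= 0) {
    stop("no interior fixed point found (root lies on the simplex boundary)",
         call. = FALSE)
  }
  ev <- eigen(ode_jacobian(x, system), only.values = TRUE)$values
  structure(
    list(x = x, x_U = x_U, residual = res, eigenvalues = ev,
         stable = all(Re(ev) < 0), variant = system$variant),
    class = "stability_report"
  )
}

newton_polish <- function(x, system, max_iter = 60L) {
  for (it in seq_len(max_iter)) {
    f <- ode_rhs(x, system)
    if (max(abs(f)) < 1e-14) break
    J <- ode_jacobian(x, system)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    # damped update keeps the iterate inside the simplex
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      if (all(xn > 0) && sum(xn) < 1) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { xn <- x; break }
    }
    if (max(abs(xn - x)) < 1e-16) { x <- xn; break }
    x <- xn
  }
  x
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Fixed point (", x$variant, "): ",
      paste(signif(x$x, 8), collapse = ", "),
      "  x_U = ", signif(x$x_U, 8), "\n", sep = "")
  cat("  residual:", format(x$residual, digits = 3),
      "| stable:", x$stable, "\n")
  cat("  eigenvalue real parts:",
      paste(signif(Re(x$eigenvalues), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Jacobian spectrum at a fixed point
#'
#' @param system A `reaction_system`.
#' @param x Committed fractions of a fixed point (residual below
#'   `residual_tol`, checked).
#' @param residual_tol Maximum allowed `max |dx_i/dt|` at `x`.
#' @return Complex vector of the `n` Jacobian eigenvalues in committed
#'   coordinates.
#' @export
stability_eigenvalues <- function(system, x, residual_tol = 1e-9) {
  res <- max(abs(ode_rhs(x, system)))
  if (res > residual_tol) {
    stop(sprintf("state is not a fixed point (residual %.3g > %g)",
                 res, residual_tol), call. = FALSE)
  }
  eigen(ode_jacobian(x, system), only.values = TRUE)$values
}

#' Time to converge to a reference allocation
#'
#' Integrates the mean-field system on a logarithmically spaced grid and
#' reports the first *sustained* passage of the squared distance
#' `R^2 = sum_i (x_i(t) - ref_i)^2` (committed fractions only) below `tol`:
#' the earliest time after which R^2 stays below `tol` up to the horizon.
#' The crossing is refined by log-log interpolation between grid points.
#'
#' @param system A `reaction_system`.
#' @param init Initial committed fractions (default fully uncommitted).
#' @param target Reference allocation: numeric vector of `n` committed
#'   fractions. Defaults to the quality-proportional target of
#'   [target_distribution()].
#' @param tol Squared-distance threshold (default `1e-4`).
#' @param horizon Maximum integration time searched.
#' @param points_per_decade Density of the logarithmic output grid.
#' @param check_fixed_point When `TRUE` and `target` is the default target,
#'   verify first that the system's fixed point itself satisfies
#'   `R^2 < tol` (otherwise no finite convergence time exists).
#' @return The convergence time (0 when the initial state already
#'   qualifies). Errors if the trajectory has not converged by `horizon`.
#' @export
convergence_time <- function(system, init = NULL, target = NULL, tol = 1e-4,
                             horizon = 1e7, points_per_decade = 200L,
                             check_fixed_point = TRUE) {
  stopifnot(inherits(system, "reaction_system"), tol > 0, horizon > 0)
  n <- system$environment$n
  if (is.null(init)) init <- default_init(system)
  if (is.null(target)) {
    target <- target_distribution(system$environment)
    if (check_fixed_point) {
      fp <- find_fixed_point(system)
      if (r2_error(fp$x, target) >= tol) {
        stop("the system's fixed point does not satisfy R^2 < tol; ",
             "no finite convergence time to this target exists", call. = FALSE)
      }
    }
  }
  if (length(target) != n) stop("'target' must have length n", call. = FALSE)

  t0 <- 1e-4
  times <- c(0, 10^seq(log10(t0), log10(horizon),
                       by = 1 / points_per_decade))
  tr <- integrate_ode(system, init = init, times = times)
  r2 <- rowSums((tr$x - matrix(target, nrow(tr$x), n, byrow = TRUE))^2)

  suffix_max <- rev(cummax(rev(r2)))
  k <- which(suffix_max < tol)[1L]
  if (is.na(k)) {
    stop(sprintf("not converged: R^2 still %.3g at horizon %g",
                 r2[length(r2)], horizon), call. = FALSE)
  }
  if (k == 1L) return(0)
  # refine the crossing between grid points k-1 and k
  t1 <- times[k - 1L]; t2 <- times[k]
  r1 <- r2[k - 1L]; r2k <- r2[k]
  if (t1 > 0 && r1 > tol && r2k > 0 && r2k < tol) {
    lt <- log10(t1) + (log10(tol) - log10(r1)) /
      (log10(r2k) - log10(r1)) * (log10(t2) - log10(t1))
    10^lt
  } else {
    t2
  }
}
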