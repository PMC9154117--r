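#' Define a patch environment
#'
#' A foraging environment is a set of `n` forage patches, each with a positive
#' quality `q_i`. Qualities are dimensionless and need not be normalised:
#' only quality ratios enter the target distribution.
#'
#' @param qualities Numeric vector of positive, finite patch qualities.
#' @return An object of class `patch_environment` with fields `n` and
#'   `qualities`.
#' @examples
#' env <- make_environment(c(0.75, 0.5, 0.25))
#' target_distribution(env)
#' @export
make_environment <- function(qualities) {
  if (length(qualities) == 0) {
    stop("'qualities' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(qualities) || anyNA(qualities) || any(!is.finite(qualities))) {
    stop("'qualities' must be finite numeric values", call. = FALSE)
  }
  if (any(qualities <= 0)) {
    stop("all patch qualities must be strictly positive", call. = FALSE)
  }
  structure(
    list(n = length(qualities), qualities = as.numeric(qualities)),
    class = "patch_environment"
  )
}

#' @export
print.patch_environment <- function(x, ...) {
  cat("Patch environment:", x$n, "patches\n")
  cat("  qualities:", paste(signif(x$qualities, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Quality-proportional target distribution
#'
#' The desired allocation of committed foragers across patches: each patch
#' receives a fraction of the colony proportional to its relative quality,
#' `x_i* = q_i / sum_j q_j`. The target is defined over committed foragers
#' only; the residual uncommitted fraction at equilibrium is a model outcome,
#' not part of the target.
#'
#' @param env A [make_environment()] object.
#' @return Numeric vector of length `n` on the open simplex (sums to 1).
#' @export
target_distribution <- function(env) {
  stopifnot(inherits(env, "patch_environment"))
  env$qualities / sum(env$qualities)
}

#' Individual-level rate parameters for a model variant
#'
#' Collects the abandonment rate `a`, the average recruitment strength `r`,
#' the stop-signal strength `z`, and the derived recruitment coefficient
#' `rho` and per-patch recruitment rates `r_i`. The per-patch rates are a
#' pure function of the variant: `r_i = rho` (quality-insensitive) for the
#' positive-only model, `r_i = rho * q_i` (quality-sensitive) with negative
#' feedback, and `r_i = 0` for the asocial baseline. By default `rho` is set
#' by [equalise_recruitment()] so that the patch-averaged recruitment rate
#' equals `r` in every social variant.
#'
#' @param env A [make_environment()] object.
#' @param variant One of `"positive_only"`, `"negative_feedback"`,
#'   `"asocial"`.
#' @param a Abandonment (leak) rate, per unit time, `a >= 0`.
#' @param r Average recruitment strength, per unit time (ignored for the
#'   asocial variant).
#' @param z Stop-signal strength, per unit time. Must be positive for the
#'   negative-feedback variant and zero otherwise.
#' @param rho Optional explicit recruitment coefficient; when `NULL` it is
#'   derived from `r` via [equalise_recruitment()].
#' @return An object of class `rate_parameters`.
#' @export
rate_parameters <- function(env, variant, a, r = 0, z = 0, rho = NULL) {
  variant <- match.arg(variant, .variants)
  stopifnot(inherits(env, "patch_environment"))
  for (nm in c("a", "r", "z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a single non-negative finite number", nm),
           call. = FALSE)
    }
  }
  if (variant == "negative_feedback") {
    if (z <= 0) {
      stop("the negative-feedback variant requires a stop-signal strength z > 0",
           call. = FALSE)
    }
  } else if (z != 0) {
    stop(sprintf("variant '%s' must have z = 0 (got z = %g)", variant, z),
         call. = FALSE)
  }
  if (is.null(rho)) {
    rho <- equalise_recruitment(r, env, variant)
  } else {
    if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho < 0) {
      stop("'rho' must be a single non-negative finite number", call. = FALSE)
    }
  }
  r_i <- switch(variant,
    positive_only     = rep(rho, env$n),
    negative_feedback = rho * env$qualities,
    asocial           = rep(0, env$n)
  )
  if (variant != "asocial" && any(r_i <= env$qualities)) {
    # the models are meant for the regime where social recruitment is much
    # more efficient than independent discovery; not a hard requirement
    message("note: some per-patch recruitment rates r_i do not exceed the ",
            "discovery rates q_i; the model is usually studied with r_i >> q_i")
  }
  structure(
    list(variant = variant, a = a, r = r, rho = rho, z = z, r_i = r_i),
    class = "rate_parameters"
  )
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Rate parameters (", x$variant, ")\n", sep = "")
  cat(sprintf("  a = %g, r = %g, rho = %g, z = %g\n", x$a, x$r, x$rho, x$z))
  cat("  r_i:", paste(signif(x$r_i, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Compile a model variant into a reaction system
#'
#' Builds the mass-action reaction list shared by the ODE and SSA engines.
#' Each patch `i` contributes: independent discovery `U -> i` at rate `q_i`
#' and independent abandonment `i -> U` at rate `a` (all variants);
#' recruitment `U + i -> 2i` at rate `r_i` (social variants); and
#' stop signalling `i + i -> U + i` at rate `z` (negative feedback only).
#' Stop signalling is self-inhibition: it only acts between two foragers
#' committed to the same patch, never across patches. Every reaction moves
#' exactly one individual between species, so total population is conserved.
#'
#' @param variant One of `"positive_only"`, `"negative_feedback"`,
#'   `"asocial"`.
#' @param env A [make_environment()] object.
#' @param rates A [rate_parameters()] object built for the same variant.
#' @return An object of class `reaction_system` with the environment, rates
#'   and a reaction table (one row per reaction channel) plus the
#'   stoichiometry matrix used by both engines.
#' @examples
#' sys <- foraging_model("negative_feedback", c(0.75, 0.5, 0.25),
#'                       a = 1e-3, r = 100, z = 3.1)
#' print(sys)
#' @export
build_model <- function(variant, env, rates) {
  variant <- match.arg(variant, .variants)
  stopifnot(inherits(env, "patch_environment"), inherits(rates, "rate_parameters"))
  if (rates$variant != variant) {
    stop(sprintf("rates were built for variant '%s', not '%s'",
                 rates$variant, variant), call. = FALSE)
  }
  n <- env$n
  q <- env$qualities
  U <- 1L
  pat <- function(i) 1L + i

  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "discovery", patch = i, rate = q[i],
      r1 = U, r2 = NA_integer_, src = U, dst = pat(i)
    )
    rows[[length(rows) + 1L]] <- data.frame(
      type = "abandonment", patch = i, rate = rates$a,
      r1 = pat(i), r2 = NA_integer_, src = pat(i), dst = U
    )
    if (variant != "asocial") {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "recruitment", patch = i, rate = rates$r_i[i],
        r1 = U, r2 = pat(i), src = U, dst = pat(i)
      )
    }
    if (variant == "negative_feedback") {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "stop_signal", patch = i, rate = rates$z,
        r1 = pat(i), r2 = pat(i), src = pat(i), dst = U
      )
    }
  }
  reactions <- do.call(rbind, rows)
  rownames(reactions) <- NULL

  # net state change of each reaction over species (U, patch_1, .., patch_n)
  stoich <- matrix(0, nrow = nrow(reactions), ncol = n + 1L)
  for (k in seq_len(nrow(reactions))) {
    stoich[k, reactions$src[k]] <- stoich[k, reactions$src[k]] - 1
    stoich[k, reactions$dst[k]] <- stoich[k, reactions$dst[k]] + 1
  }
  colnames(stoich) <- species_names(n)

  expected <- switch(variant,
    asocial = 2L * n, positive_only = 3L * n, negative_feedback = 4L * n)
  stopifnot(nrow(reactions) == expected)

  structure(
    list(environment = env, rates = rates, variant = variant,
         reactions = reactions, stoich = stoich),
    class = "reaction_system"
  )
}

#' One-call model constructor
#'
#' Convenience wrapper building environment, rates and reaction system in
#' one step.
#'
#' @inheritParams rate_parameters
#' @param qualities Numeric vector of positive patch qualities.
#' @return A `reaction_system` (see [build_model()]).
#' @export
foraging_model <- function(variant, qualities, a, r = 0, z = 0, rho = NULL) {
  env <- make_environment(qualities)
  build_model(variant, env, rate_parameters(env, variant, a, r, z, rho))
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("Reaction system:", x$variant, "variant,",
      x$environment$n, "patches,", nrow(x$reactions), "reactions\n")
  cat(format_reactions(x), sep = "\n")
  invisible(x)
}

#' Human-readable reaction listing
#'
#' @param system A `reaction_system`.
#' @return Character vector, one formatted line per reaction.
#' @export
format_reactions <- function(system) {
  rx <- system$reactions
  lhs <- function(k) {
    if (is.na(rx$r2[k])) species_names(system$environment$n)[rx$r1[k]]
    else paste(species_names(system$environment$n)[c(rx$r1[k], rx$r2[k])],
               collapse = " + ")
  }
  rhs <- function(k) {
    sp <- species_names(system$environment$n)
    switch(rx$type[k],
      discovery   = sp[rx$dst[k]],
      abandonment = sp[rx$dst[k]],
      recruitment = paste0("2 ", sp[rx$dst[k]]),
      stop_signal = paste(sp[rx$dst[k]], sp[rx$r2[k]], sep = " + ")
    )
  }
  vapply(seq_len(nrow(rx)), function(k) {
    sprintf("  [%s %d] %s -> %s  (rate %g)",
            rx$type[k], rx$patch[k], lhs(k), rhs(k), rx$rate[k])
  }, character(1))
}

#' Write a model configuration file
#'
#' Serialises the defining parameters of a reaction system (variant,
#' qualities, a, r, z, rho) to YAML so a model can be rebuilt exactly.
#'
#' @param system A `reaction_system`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(system, path) {
  stopifnot(inherits(system, "reaction_system"))
  cfg <- list(
    variant = system$variant,
    qualities = system$environment$qualities,
    a = system$rates$a,
    r = system$rates$r,
    z = system$rates$z,
    rho = system$rates$rho
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a model configuration file
#'
#' @param path YAML file with keys `variant`, `qualities`, `a`, `r`, `z` and
#'   optional `rho` (when present it overrides recruitment equalisation).
#' @return A `reaction_system`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("variant", "qualities", "a")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  foraging_model(cfg$variant, as.numeric(cfg$qualities), a = cfg$a,
                 r = if (is.null(cfg$r)) 0 else cfg$r,
                 z = if (is.null(cfg$z)) 0 else cfg$z,
                 rho = cfg$rho)
}
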