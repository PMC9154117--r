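# canonical scenario systems used across test files
canonical_env <- function() make_environment(c(0.75, 0.5, 0.25))

canonical_positive <- function() {
  foraging_model("positive_only", c(0.75, 0.5, 0.25), a = 1e-3, r = 100)
}

canonical_negative <- function() {
  foraging_model("negative_feedback", c(0.75, 0.5, 0.25), a = 1e-3, r = 100,
                 z = 3.1)
}

# central finite-difference Jacobian, the independent oracle for the
# analytic one
fd_jacobian <- function(x, system, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (ode_rhs(x + e, system) - ode_rhs(x - e, system)) / (2 * h)
  }
  J
}

# random interior committed state (keeps a margin from the boundary)
random_interior <- function(n) {
  g <- rgamma(n + 1, shape = 2)
  (0.9 * g / sum(g))[-1]
}
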