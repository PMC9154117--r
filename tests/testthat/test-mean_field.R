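test_that("the right-hand side evaluates the mass-action terms", {
  sys <- foraging_model("positive_only", c(0.75, 0.5), a = 1e-3, r = 100)
  # hand evaluation: q1 xU - a x1 + rho xU x1 with xU = 0.3
  expect_equal(ode_rhs(c(0.4, 0.3), sys)[1],
               0.75 * 0.3 - 0.001 * 0.4 + 100 * 0.3 * 0.4,
               tolerance = 1e-12)

  # fully uncommitted: only discovery acts, dx_i = q_i, for every variant
  q <- c(0.75, 0.5, 0.25)
  for (sys in list(foraging_model("asocial", q, a = 1e-3),
                   foraging_model("positive_only", q, a = 1e-3, r = 100),
                   canonical_negative())) {
    expect_equal(ode_rhs(rep(0, 3), sys), q)
  }
  expect_error(ode_rhs(c(0.1, 0.2), canonical_negative()), "3 committed")
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(21)
  for (sys in list(canonical_positive(), canonical_negative(),
                   foraging_model("asocial", c(0.3, 1.2), a = 0.01))) {
    n <- sys$environment$n
    for (rep in 1:5) {
      x <- random_interior(n)
      expect_lt(max(abs(ode_jacobian(x, sys) - fd_jacobian(x, sys))), 1e-5)
    }
  }
})

test_that("asocial single-patch dynamics match the linear closed form", {
  q <- 1; a <- 1e-3
  sys <- foraging_model("asocial", q, a = a)
  tr <- integrate_ode(sys, t_end = 10)
  xstar <- q / (q + a)
  expect_equal(tr$x[, 1], xstar * (1 - exp(-(q + a) * tr$times)),
               tolerance = 1e-8)
  # eigenvalue of the scalar linear ODE
  fp <- find_fixed_point(sys)
  expect_equal(Re(fp$eigenvalues), -(q + a), tolerance = 1e-12)
  expect_equal(stability_eigenvalues(sys, fp$x), fp$eigenvalues)
})

test_that("positive-only fixed point has the closed-form uncommitted residual", {
  sys <- foraging_model("positive_only", c(0.75, 0.5), a = 1e-3, r = 100)
  fp <- find_fixed_point(sys)
  expect_equal(fp$x_U, 9.8765432e-06, tolerance = 1e-6)
  expect_equal(fp$x[1] / fp$x[2], 0.75 / 0.5, tolerance = 1e-12)
  expect_true(fp$stable)
  expect_lt(max(abs(ode_rhs(fp$x, sys))), 1e-10)
})

test_that("positive-only fixed points stay quality-proportional across parameters", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(2:5, 1)
    q <- runif(n, 0.1, 1)
    sys <- foraging_model("positive_only", q, a = 10^runif(1, -4, -1),
                          r = 10^runif(1, 1, 2.5))
    x <- find_fixed_point(sys)$x
    expect_lt(max(abs(outer(x, q) - outer(q, x))), 1e-10)
  }
})

test_that("stop signalling at z = a*rho gives an exactly proportional fixed point", {
  env <- canonical_env()
  target <- target_distribution(env)
  sys <- foraging_model("negative_feedback", c(0.75, 0.5, 0.25), a = 1e-3,
                        r = 100, z = exact_z(1e-3, 200))
  fp <- find_fixed_point(sys)
  expect_lt(allocation_r2(fp$x, target), 1e-13)
  # the raw distance keeps the predicted uncommitted-residual floor
  Q <- sum(env$qualities); a <- 1e-3
  expect_equal(r2_error(fp$x, target), (a / (a + Q))^2 * sum(target^2),
               tolerance = 1e-6)
})

test_that("canonical negative-feedback fixed point is stable and near the target", {
  fp <- find_fixed_point(canonical_negative())
  expect_true(fp$stable)
  r2 <- r2_error(fp$x, target_distribution(canonical_env()))
  expect_gt(r2, 0)
  expect_lt(r2, 1e-4)
})

test_that("equal qualities give equal committed fractions for every variant", {
  q <- rep(0.4, 4)
  for (sys in list(foraging_model("asocial", q, a = 1e-3),
                   foraging_model("positive_only", q, a = 1e-3, r = 100),
                   foraging_model("negative_feedback", q, a = 1e-3, r = 100,
                                  z = 1))) {
    x <- find_fixed_point(sys)$x
    expect_lt(diff(range(x)), 1e-12)
  }
})

test_that("trajectories conserve the simplex and stay non-negative", {
  for (sys in list(canonical_positive(), canonical_negative())) {
    tr <- integrate_ode(sys, t_end = 400)
    expect_lt(max(abs(tr$x_U + rowSums(tr$x) - 1)), 1e-9)
    expect_gt(min(tr$x, tr$x_U), -1e-9)
  }
})

test_that("integration input validation and failure reporting work", {
  sys <- canonical_positive()
  expect_error(integrate_ode(sys, t_end = -1), "t_end")
  expect_error(integrate_ode(sys, t_end = 10, rel_tol = 0), "positive")
  expect_error(integrate_ode(sys, times = c(0, 1, 1)), "strictly increasing")
  expect_error(integrate_ode(sys, init = c(0.7, 0.7, 0.2), t_end = 1),
               "sum to at most 1")
  expect_error(stability_eigenvalues(sys, c(0.3, 0.2, 0.1)), "not a fixed point")
})

test_that("convergence time is zero at the fixed point and finite from scratch", {
  sys <- canonical_negative()
  fp <- find_fixed_point(sys)
  expect_equal(convergence_time(sys, init = fp$x, target = fp$x,
                                check_fixed_point = FALSE), 0)
  ct <- convergence_time(sys, target = fp$x, check_fixed_point = FALSE)
  expect_gt(ct, 0)
  expect_lt(ct, 100)
})

test_that("convergence to the target is refused when the fixed point misses it", {
  # at z = 8 the fixed point sits further than 1e-4 from the target
  sys <- foraging_model("negative_feedback", c(0.75, 0.5, 0.25), a = 1e-3,
                        r = 100, z = 8)
  expect_gt(r2_error(find_fixed_point(sys)$x,
                     target_distribution(canonical_env())), 1e-4)
  expect_error(convergence_time(sys), "no finite convergence time")
})

test_that("trajectories export to tidy long format", {
  tr <- integrate_ode(canonical_negative(), t_end = 10)
  df <- as.data.frame(tr)
  expect_named(df, c("time", "species", "fraction"))
  expect_equal(nrow(df), length(tr$times) * 4L)
  expect_setequal(unique(df$species), c("U", "patch_1", "patch_2", "patch_3"))
})
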