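test_that("environment construction validates qualities", {
  env <- make_environment(c(0.75, 0.5, 0.25))
  expect_equal(env$n, 3L)
  expect_equal(env$qualities, c(0.75, 0.5, 0.25))
  expect_equal(make_environment(1.0)$n, 1L)

  expect_error(make_environment(numeric(0)), "non-empty")
  expect_error(make_environment(c(0.75, -0.1)), "positive")
  expect_error(make_environment(c(0.5, 0)), "positive")
  expect_error(make_environment(c(0.5, NA)), "finite")
  expect_error(make_environment(c(0.5, Inf)), "finite")
})

test_that("target distribution is quality-proportional", {
  expect_equal(target_distribution(make_environment(c(0.75, 0.5, 0.25))),
               c(0.5, 1 / 3, 1 / 6))
  expect_equal(target_distribution(make_environment(rep(0.3, 5))), rep(0.2, 5))
  expect_equal(target_distribution(make_environment(5)), 1.0)
})

test_that("target distribution is scale invariant and permutation equivariant", {
  set.seed(11)
  for (rep in 1:20) {
    q <- runif(sample(2:6, 1), 0.05, 2)
    t1 <- target_distribution(make_environment(q))
    expect_equal(sum(t1), 1)
    expect_equal(target_distribution(make_environment(q * runif(1, 0.1, 50))),
                 t1)
    p <- sample(length(q))
    expect_equal(target_distribution(make_environment(q[p])), t1[p])
  }
})

test_that("reaction counts follow the variant formula for n = 1..10", {
  for (n in 1:10) {
    q <- seq_len(n) / n
    expect_equal(nrow(foraging_model("asocial", q, a = 1e-3)$reactions), 2L * n)
    expect_equal(nrow(foraging_model("positive_only", q, a = 1e-3,
                                     r = 100)$reactions), 3L * n)
    expect_equal(nrow(foraging_model("negative_feedback", q, a = 1e-3, r = 100,
                                     z = 1)$reactions), 4L * n)
  }
})

test_that("every compiled reaction conserves the number of individuals", {
  for (variant in c("asocial", "positive_only", "negative_feedback")) {
    sys <- foraging_model(variant, c(0.75, 0.5, 0.25), a = 1e-3,
                          r = if (variant == "asocial") 0 else 100,
                          z = if (variant == "negative_feedback") 3.1 else 0)
    expect_true(all(rowSums(sys$stoich) == 0))
    expect_true(all(abs(sys$stoich) <= 1))
  }
})

test_that("the compiled reaction list matches the model definition", {
  sys <- canonical_negative()
  rx <- sys$reactions
  expect_equal(nrow(rx), 12L)
  expect_equal(sort(unique(rx$type)),
               c("abandonment", "discovery", "recruitment", "stop_signal"))
  # discovery at q_i, abandonment at a, recruitment at rho q_i, stop at z
  expect_equal(rx$rate[rx$type == "discovery"], c(0.75, 0.5, 0.25))
  expect_equal(rx$rate[rx$type == "abandonment"], rep(1e-3, 3))
  expect_equal(rx$rate[rx$type == "recruitment"], 200 * c(0.75, 0.5, 0.25))
  expect_equal(rx$rate[rx$type == "stop_signal"], rep(3.1, 3))
  # stop signalling is same-species self-inhibition, never cross-patch
  stop_rows <- rx[rx$type == "stop_signal", ]
  expect_equal(stop_rows$r1, stop_rows$r2)

  expect_equal(nrow(foraging_model("asocial", c(1, 1), a = 0.5)$reactions), 4L)
})

test_that("variant and rate consistency is enforced", {
  env <- make_environment(c(0.75, 0.5, 0.25))
  expect_error(rate_parameters(env, "positive_only", a = 1e-3, r = 100, z = 3.1),
               "z = 0")
  expect_error(rate_parameters(env, "asocial", a = 1e-3, z = 0.1), "z = 0")
  expect_error(rate_parameters(env, "negative_feedback", a = 1e-3, r = 100,
                               z = 0), "z > 0")
  expect_error(rate_parameters(env, "positive_only", a = -1, r = 100),
               "non-negative")
  # rates built for one variant cannot be compiled under another
  rates <- rate_parameters(env, "positive_only", a = 1e-3, r = 100)
  expect_error(build_model("asocial", env, rates), "variant")
})

test_that("derived per-patch recruitment follows the variant rule", {
  env <- make_environment(c(0.75, 0.5, 0.25))
  expect_equal(rate_parameters(env, "positive_only", a = 1e-3, r = 100)$r_i,
               rep(100, 3))
  rn <- rate_parameters(env, "negative_feedback", a = 1e-3, r = 100, z = 3.1)
  expect_equal(rn$rho, 200)
  expect_equal(rn$r_i, 200 * c(0.75, 0.5, 0.25))
  expect_equal(rate_parameters(env, "asocial", a = 1e-3)$r_i, rep(0, 3))
})

test_that("model configuration round-trips through YAML", {
  sys <- canonical_negative()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(sys, f)
  sys2 <- read_model_config(f)
  expect_identical(sys$reactions, sys2$reactions)
  expect_identical(sys$variant, sys2$variant)
  expect_equal(sys$rates$rho, sys2$rates$rho)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(variant = "asocial"), bad)
  expect_error(read_model_config(bad), "missing keys")
})

test_that("reaction listing is human readable", {
  lines <- format_reactions(canonical_negative())
  expect_length(lines, 12L)
  expect_match(lines[1], "U -> patch_1")
  expect_match(lines[grep("stop_signal", lines)[1]], "patch_1 -> U \\+ patch_1")
})
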