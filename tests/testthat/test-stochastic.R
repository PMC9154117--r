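test_that("propensities implement the master-equation rate laws", {
  sys <- canonical_negative()
  S <- 200L
  # everyone uncommitted: only discovery channels are live, at q_i * S
  p0 <- propensities(c(S, 0L, 0L, 0L), sys)
  types <- sys$reactions$type
  expect_equal(p0[types == "discovery"], c(0.75, 0.5, 0.25) * S)
  expect_true(all(p0[types != "discovery"] == 0))

  # a single committed individual cannot stop-signal itself
  p1 <- propensities(c(S - 1L, 1L, 0L, 0L), sys)
  expect_equal(p1[types == "stop_signal"], rep(0, 3))

  # generic state against the closed-form rate laws
  x <- c(20L, 100L, 50L, 30L)
  p <- propensities(x, sys)
  expect_equal(p[types == "discovery"], c(0.75, 0.5, 0.25) * 20)
  expect_equal(p[types == "abandonment"], 1e-3 * c(100, 50, 30))
  expect_equal(p[types == "recruitment"],
               (200 * c(0.75, 0.5, 0.25) / 200) * 20 * c(100, 50, 30))
  expect_equal(p[types == "stop_signal"],
               (3.1 / 200) * c(100 * 99, 50 * 49, 30 * 29))

  expect_error(propensities(c(10L, 5L), sys), "4 entries")
  expect_error(propensities(c(10L, -1L, 2L, 3L), sys), "non-negative")
})

test_that("scaled propensities reproduce the mean-field rates as S grows", {
  sys <- canonical_negative()
  frac <- c(0.25, 0.4, 0.2, 0.15)
  err <- vapply(c(1e2, 1e3, 1e4), function(S) {
    counts <- round(frac * S)
    dx_ssa <- drop(crossprod(sys$stoich, propensities(counts, sys)))[-1] /
      sum(counts)
    max(abs(dx_ssa - ode_rhs(counts[-1] / sum(counts), sys)))
  }, numeric(1))
  expect_lt(err[3], 1e-3)
  # O(1/S): each tenfold increase in S cuts the discrepancy tenfold
  expect_equal(err[1] / err[2], 10, tolerance = 0.1)
  expect_equal(err[2] / err[3], 10, tolerance = 0.1)
})

test_that("runs are reproducible given a seed and differ across seeds", {
  sys <- canonical_negative()
  r1 <- gillespie_run(sys, S = 200, t_end = 50, seed = 42)
  r2 <- gillespie_run(sys, S = 200, t_end = 50, seed = 42)
  r3 <- gillespie_run(sys, S = 200, t_end = 50, seed = 43)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$n_events, r2$n_events)
  expect_false(identical(r1$counts, r3$counts))
})

test_that("population count is conserved after every single event", {
  sys <- canonical_negative()
  r <- gillespie_run(sys, S = 150, t_end = 5, seed = 7, record_events = TRUE)
  expect_gt(nrow(r$events), 100)
  x <- r$counts[1, ]
  for (k in seq_len(nrow(r$events))) {
    x[r$events$from[k]] <- x[r$events$from[k]] - 1L
    x[r$events$to[k]] <- x[r$events$to[k]] + 1L
    expect_identical(sum(x), 150L)
    expect_true(all(x >= 0L))
  }
  # grid-recorded states also conserve the population
  expect_true(all(rowSums(r$counts) == 150L))
})

test_that("ensemble mean tracks the immigration-death closed form", {
  # asocial single patch, colony starting fully committed:
  # E[x1(t)] = q/(q+a) + a/(q+a) exp(-(q+a) t)
  q <- 1; a <- 0.5
  sys <- foraging_model("asocial", q, a = a)
  ts <- c(0, 1, 2, 4)
  e <- run_ensemble(sys, S = 100, n_runs = 1000, t_end = 4, master_seed = 7,
                    init = c(0L, 100L), record_times = ts)
  for (i in 2:4) {
    fr <- e$counts[i, 2, ] / 100
    expected <- q / (q + a) + a / (q + a) * exp(-(q + a) * ts[i])
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - expected), 3 * se + 1e-12)
  }
})

test_that("inter-event waiting times are exponential with the total propensity", {
  sys <- canonical_negative()
  state <- c(20L, 100L, 50L, 30L)
  total <- sum(propensities(state, sys))
  waits <- vapply(seq_len(2000), function(k) {
    r <- gillespie_run(sys, init = state, t_end = 1e6, seed = 50000 + k,
                       record_times = 0, record_events = TRUE, max_events = 1)
    r$events$time[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", rate = total))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensembles are reproducible and reduce to single runs", {
  sys <- canonical_negative()
  e1 <- run_ensemble(sys, S = 100, n_runs = 3, t_end = 20, master_seed = 99)
  e2 <- run_ensemble(sys, S = 100, n_runs = 3, t_end = 20, master_seed = 99)
  expect_identical(e1$counts, e2$counts)
  expect_equal(e1$seeds, c(99L, 100L, 101L))

  single <- gillespie_run(sys, S = 100, t_end = 20, seed = 99)
  expect_identical(unname(e1$counts[, , 1]), unname(single$counts))

  # byte-identical CSV export for a fixed configuration
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tidy_csv(e1, f1)
  write_tidy_csv(e2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("state_at follows the left-hold right-continuous convention", {
  sys <- foraging_model("asocial", 1, a = 0.1)
  r <- gillespie_run(sys, S = 10, t_end = 50, seed = 5, record_events = TRUE)
  expect_identical(state_at(r, 0), c(10L, 0L))
  t1 <- r$events$time[1]
  # just before the first event: still the initial state
  expect_identical(state_at(r, t1 * (1 - 1e-9)), c(10L, 0L))
  # exactly at the event time: the post-event state
  expect_identical(state_at(r, t1), c(9L, 1L))
  expect_identical(sum(state_at(r, 25)), 10L)
  expect_error(state_at(r, -1), "horizon")
  expect_error(state_at(r, 51), "horizon")
})

test_that("stationary fluctuations scale inversely with population size", {
  sys <- canonical_negative()
  sizes <- c(50, 200, 800)
  v <- vapply(sizes, function(S) {
    e <- run_ensemble(sys, S = S, n_runs = 100, t_end = 400,
                      master_seed = 20260926)
    mean(ensemble_variance(e, 400))
  }, numeric(1))
  slope <- coef(lm(log(v) ~ log(sizes)))[[2]]
  expect_lt(abs(slope + 1), 0.3)
})

test_that("the event cap stops a run early without corrupting it", {
  sys <- canonical_negative()
  r <- gillespie_run(sys, S = 50, t_end = 1e6, seed = 1, record_times = 0,
                     max_events = 10, record_events = TRUE)
  expect_equal(r$n_events, 10)
  expect_false(r$absorbed)
})
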