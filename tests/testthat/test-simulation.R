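# Fixed-step RK4 with pinned operation order, and the run loop.

test_that("RK4 leaves the state untouched for a zero field", {
  y <- c(0.1, -2.5, 1e10)
  expect_identical(rk4_step(function(t, y) y * 0, 0, y, 0.01), y)
})

test_that("RK4 reproduces its closed-form update for linear decay", {
  # y' = -y: one RK4 step is multiplication by 1 - h + h^2/2 - h^3/6 + h^4/24
  h <- 0.1
  got <- rk4_step(function(t, y) -y, 0, 1, h)
  want <- 1 - h + h^2 / 2 - h^3 / 6 + h^4 / 24
  expect_lt(abs(got - want), 2 * .Machine$double.eps)
  expect_equal(got, 0.9048375, tolerance = 1e-12)
})

test_that("RK4 is Simpson-exact for a time-only cubic integrand", {
  for (h in c(0.1, 0.02, 1)) {
    got <- rk4_step(function(t, y) 3 * t^2, 0, 0, h)
    expect_lt(abs(got - h^3), 4 * .Machine$double.eps * max(1, h^3))
  }
})

test_that("settings validation enforces the step bookkeeping", {
  s <- simulation_settings("0.01", 100, 10L)
  expect_identical(s$n_steps, 10000L)
  expect_error(simulation_settings("0.01", 100.005), "multiple")
  expect_error(simulation_settings("0", 100), "positive")
  expect_error(simulation_settings("0.01", 100, 0L), "record_stride")
})

test_that("identical runs are bitwise identical, and zero duration records
           only the initial sample", {
  spec <- scenario_spec("ALL_EXC", "RND", seed = HH_SEED, N = 5L,
                        settings = tiny_settings(50))
  t1 <- run_scenario(spec)
  t2 <- run_scenario(spec)
  expect_identical(t1$A, t2$A)
  expect_identical(t1$S, t2$S)
  expect_identical(t1$times, t2$times)
  spec0 <- scenario_spec("ALL_EXC", "RND", seed = HH_SEED, N = 5L,
                         settings = simulation_settings("0.01", 0))
  t0 <- run_scenario(spec0)
  expect_identical(length(t0$times), 1L)
  expect_identical(t0$times, 0)
})

test_that("sample times are fresh products of the step index and dt", {
  spec <- scenario_spec("ALL_EXC", "RND", seed = HH_SEED, N = 3L,
                        settings = tiny_settings(20, 7L))
  tr <- run_scenario(spec)
  idx <- seq(0L, 2000L, by = 7L)
  expect_identical(tr$times, idx * 0.01)
})

test_that("a numerically exploding run aborts with step and neuron info", {
  p <- model_parameters()
  cfg <- network_configuration(4, "ALL_EXC", rep("5", 4), "NAIVE")
  s <- simulation_settings("50", 5000)  # absurd step: RK4 blows up
  expect_error(run_simulation(p, cfg, s), "non-finite state at step")
})

test_that("exact singular membrane potentials abort unless limits are chosen", {
  p <- model_parameters()
  cfg <- network_configuration(2, "ALL_EXC", rep("0", 2), "NAIVE")
  s <- simulation_settings("0.01", 1)
  ic <- list(V = "10", n = "0.3", a = "0", s = "1")
  expect_error(run_simulation(p, cfg, s, initial_conditions = ic),
               "alpha_n")
  tr <- run_simulation(p, cfg, s, initial_conditions = ic,
                       singularity = "limit")
  expect_true(all(is.finite(tr$A)))
})

test_that("relabelling neurons cannot change order-invariant runs", {
  # permuting the applied currents permutes neuron labels; with every
  # cross-neuron reduction correctly rounded the traces must be bitwise equal
  for (srt in c("RND", "ASD", "DESC")) {
    spec <- scenario_spec("ALL_EXC", srt, seed = HH_SEED, N = 10L,
                          summation = "REPRODUCIBLE",
                          settings = tiny_settings(100))
    tr <- run_scenario(spec)
    if (srt == "RND") ref <- tr
    expect_identical(tr$A, ref$A)
    expect_identical(tr$S, ref$S)
  }
})

test_that("high-precision runs carry full-precision samples and agree with
           binary64 at early times", {
  spec_h <- scenario_spec("ALL_EXC", "RND", seed = HH_SEED, N = 5L,
                          precision = hfpp(40L),
                          settings = tiny_settings(10, 100L))
  spec_d <- scenario_spec("ALL_EXC", "RND", seed = HH_SEED, N = 5L,
                          settings = tiny_settings(10, 100L))
  th <- run_scenario(spec_h)
  td <- run_scenario(spec_d)
  expect_false(is.null(th$A_str))
  expect_identical(length(th$A_str), length(th$times))
  # over 10 ms the backends agree far beyond plotting accuracy
  expect_lt(max(abs(th$A - td$A)), 1e-11)
  # and the HFPP trace is itself deterministic
  th2 <- run_scenario(spec_h)
  expect_identical(th$A_str, th2$A_str)
})
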