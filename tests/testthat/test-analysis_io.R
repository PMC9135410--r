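# Divergence analysis, episode detection, and bit-exact trace files.

fake_trace <- function(times, A, S = rep(0.5, length(A))) {
  structure(list(times = times, A = A, S = S,
                 meta = list(precision = "DFPP")), class = "hh_trace")
}

test_that("absolute error series is pointwise, symmetric, and grid-checked", {
  t <- seq(0, 1, by = 0.1)
  a <- fake_trace(t, rep(0.5, 11))
  b <- fake_trace(t, rep(0.25, 11))
  expect_identical(absolute_error_series(a, a)$epsilon, rep(0, 11))
  expect_identical(absolute_error_series(a, b)$epsilon, rep(0.25, 11))
  expect_identical(absolute_error_series(a, b)$epsilon,
                   absolute_error_series(b, a)$epsilon)
  cc <- fake_trace(seq(0, 2, by = 0.2), rep(0.5, 11))
  expect_error(absolute_error_series(a, cc), "grids")
})

test_that("first divergence uses strict exceedance of the threshold", {
  t <- seq(0, 0.1, by = 0.01)
  err <- data.frame(time_ms = t, epsilon = c(rep(0, 5), 1e-3, rep(1e-3, 5)))
  expect_identical(first_divergence_time(err, 1e-6), 0.05)
  expect_identical(first_divergence_time(data.frame(time_ms = t,
                                                    epsilon = rep(0, 11)),
                                         1e-6), NA_real_)
  # equality does not count as a crossing
  err2 <- data.frame(time_ms = c(0, 1), epsilon = c(1e-6, 2e-6))
  expect_identical(first_divergence_time(err2, 1e-6), 1)
})

test_that("crossing time is non-decreasing in the threshold", {
  set.seed(15)
  for (i in 1:20) {
    eps <- abs(cumsum(rnorm(100))) * 10^runif(1, -8, -2)
    err <- data.frame(time_ms = seq_along(eps), epsilon = eps)
    ths <- sort(10^runif(5, -9, -1))
    crossings <- vapply(ths, function(th) {
      ct <- first_divergence_time(err, th)
      if (is.na(ct)) Inf else ct
    }, numeric(1))
    finite_part <- crossings[is.finite(crossings)]
    expect_true(all(diff(finite_part) >= 0))
    # once a threshold is never crossed, no larger one is either
    expect_true(all(diff(is.finite(crossings)) <= 0))
  }
})

test_that("the divergence matrix is symmetric with NA for identical pairs", {
  t <- seq(0, 1, by = 0.1)
  a <- fake_trace(t, rep(0.5, 11))
  b <- fake_trace(t, rep(0.5, 11) + 0.9e-6)    # within threshold of a
  d <- fake_trace(t, c(rep(0.5, 6), rep(0.5 + 1.5e-6, 5)))  # crosses a only
  m <- divergence_matrix(list(a = a, b = b, d = d), 1e-6)$times_ms
  expect_true(is.na(m["a", "b"]))
  expect_identical(m["a", "d"], t[7])
  expect_identical(m, t(m))
  expect_identical(sum(is.finite(m)), 2L)  # exactly one diverging pair
})

test_that("episode detection applies hysteresis", {
  t <- seq(0, 99)
  expect_identical(nrow(detect_episodes(rep(0, 100), times = t)), 0L)
  A <- rep(0, 100); A[21:30] <- 0.6
  ep <- detect_episodes(A, times = t)
  expect_identical(nrow(ep), 1L)
  expect_identical(ep$start_ms, 20)
  # a dip that stays above the off threshold does not split the episode
  A2 <- rep(0.01, 100); A2[11:40] <- 0.6; A2[25] <- 0.15; A2[61:70] <- 0.5
  ep2 <- detect_episodes(A2, times = t)
  expect_identical(nrow(ep2), 2L)
  expect_true(all(ep2$end_ms > ep2$start_ms))
  expect_true(ep2$start_ms[2] > ep2$end_ms[1])
  expect_error(detect_episodes(A2, on_threshold = 0.1, off_threshold = 0.3),
               "on_threshold")
})

test_that("trace files round-trip binary64 samples bit for bit", {
  spec <- scenario_spec("SPLIT_80_20", "ASD", seed = HH_SEED, N = 8L,
                        settings = tiny_settings(50))
  tr <- run_scenario(spec)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_identical(back$times, tr$times)
  expect_identical(back$A, tr$A)
  expect_identical(back$S, tr$S)
  expect_identical(back$meta$split, "SPLIT_80_20")
  expect_identical(back$meta$params$gbar_syn, "3.6")
  # error against the round-tripped file is identically zero
  expect_identical(max(absolute_error_series(tr, back)$epsilon), 0)
})

test_that("high-precision traces serialize their full decimal samples", {
  spec <- scenario_spec("ALL_EXC", "RND", seed = HH_SEED, N = 4L,
                        precision = hfpp(30L),
                        settings = tiny_settings(10))
  tr <- run_scenario(spec)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_identical(back$A_str, tr$A_str)
  expect_identical(max(absolute_error_series(tr, back, exact = TRUE)$epsilon), 0)
})

test_that("malformed trace files fail with location information", {
  f <- tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_trace(f), "empty")
  writeLines(c("# precision: DFPP", "time_ms,A,S"), f)
  expect_error(read_trace(f), "no data rows")
  writeLines(c("time_ms,A,S", "0,0.5,0.5", "1,0.5"), f)
  expect_error(read_trace(f), "line 3")
})

test_that("output filenames encode and recover the run identity", {
  spec <- scenario_spec("ALL_EXC", "RND", N = 100L,
                        settings = simulation_settings("0.01", 8000))
  expect_identical(output_filename(spec),
                   "hh_dt0.01_Ne100_Ni0_vl-10.6_t8000_DFPP_RND.csv")
  spec2 <- scenario_spec("ALL_EXC", "DESC", N = 100L,
                         settings = simulation_settings("0.01", 8000))
  n1 <- strsplit(output_filename(spec), "_")[[1]]
  n2 <- strsplit(output_filename(spec2), "_")[[1]]
  expect_identical(n1[-length(n1)], n2[-length(n2)])
  p <- parse_output_filename(output_filename(spec))
  expect_identical(p$Ne, 100L)
  expect_identical(p$Ni, 0L)
  expect_identical(p$dt, "0.01")
  expect_identical(p$vl, "-10.6")
  expect_identical(p$sort, "RND")
  ph <- parse_output_filename(
    output_filename(scenario_spec("SPLIT_80_20", "ASD", N = 10L,
                                  precision = hfpp(50L),
                                  settings = tiny_settings())))
  expect_identical(ph$precision, "HFPP")
  expect_identical(ph$digits, 50L)
  expect_identical(ph$Ne, 8L)
})
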