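# Scenario matrix construction, applied-current generation, and files.

test_that("the applied-current generator is portable and in range", {
  v1 <- generate_iapp(1, 1000)
  v2 <- generate_iapp(1, 1000)
  expect_identical(v1, v2)
  x <- as.numeric(v1)
  expect_true(all(x >= -10 & x <= 5))
  expect_false(identical(v1, generate_iapp(2, 1000)))
  # uniform moment check (true mean -2.5)
  m <- mean(as.numeric(generate_iapp(1, 10000)))
  expect_gt(m, -3.0)
  expect_lt(m, -2.0)
  # 17-significant-digit strings round-trip their binary64 values
  expect_identical(sprintf("%.16e", as.numeric(v1[1:20])), v1[1:20])
})

test_that("ordering policies permute without changing the multiset", {
  v <- c("3", "-1", "2")
  expect_identical(order_iapp(v, "ASD"), c("-1", "2", "3"))
  expect_identical(order_iapp(v, "DESC"), c("3", "2", "-1"))
  expect_identical(order_iapp(v, "RND"), v)
  x <- generate_iapp(5, 50)
  expect_identical(order_iapp(x, "DESC"), rev(order_iapp(x, "ASD")))
  expect_identical(sort(as.numeric(order_iapp(x, "ASD"))),
                   sort(as.numeric(x)))
})

test_that("pool splits are proportional and positional", {
  b <- build_scenario(scenario_spec("ALL_EXC", "RND", N = 100L,
                                    settings = tiny_settings()))
  expect_identical(b$config$Ne, 100L)
  expect_identical(b$config$Ni, 0L)
  b2 <- build_scenario(scenario_spec("SPLIT_80_20", "RND", N = 100L,
                                     settings = tiny_settings()))
  expect_identical(b2$config$Ne, 80L)
  expect_identical(b2$config$Ni, 20L)
  expect_identical(b2$config$is_exc, c(rep(TRUE, 80), rep(FALSE, 20)))
  b3 <- build_scenario(scenario_spec("SPLIT_80_20", "RND", N = 10L,
                                     settings = tiny_settings()))
  expect_identical(b3$config$Ne, 8L)
  expect_identical(b3$config$Ni, 2L)
})

test_that("the six cells differ only in split and sort", {
  base <- scenario_spec("ALL_EXC", "RND", seed = 42L, N = 20L,
                        settings = tiny_settings())
  cells <- scenario_matrix(base)
  expect_identical(length(cells), 6L)
  built <- lapply(cells, build_scenario)
  # identical parameters, settings, and applied-current multiset everywhere
  for (b in built) {
    expect_identical(b$params, built[[1]]$params)
    expect_identical(b$settings, built[[1]]$settings)
    expect_identical(sort(as.numeric(b$config$Iapp)),
                     sort(as.numeric(built[[1]]$config$Iapp)))
  }
  combos <- unique(vapply(cells, function(s) paste(s$split, s$sort),
                          character(1)))
  expect_identical(length(combos), 6L)
})

test_that("scenario files round-trip every field", {
  spec <- scenario_spec("SPLIT_80_20", "DESC", seed = 9L, N = 25L,
                        precision = hfpp(40L), summation = "KAHAN",
                        settings = simulation_settings("0.02", 50, 5L),
                        initial_conditions = list(V = "1.5", n = "0.25",
                                                  a = "0", s = "0.75"),
                        params = model_parameters(k_v = "7"))
  f <- tempfile(fileext = ".yaml")
  write_scenario(spec, f)
  back <- read_scenario(f)
  expect_identical(back$split, spec$split)
  expect_identical(back$sort, spec$sort)
  expect_identical(back$seed, spec$seed)
  expect_identical(back$precision$digits, 40L)
  expect_identical(back$summation, "KAHAN")
  expect_identical(back$settings$dt, "0.02")
  expect_identical(unclass(back$params), unclass(spec$params))
  expect_identical(back$initial_conditions, spec$initial_conditions)
  expect_identical(build_scenario(back)$config$Iapp,
                   build_scenario(spec)$config$Iapp)
})

test_that("applied-current files hold one literal per line", {
  x <- generate_iapp(3, 12)
  f <- tempfile(fileext = ".txt")
  write_iapp(x, f)
  expect_identical(read_iapp(f), x)
  spec <- scenario_spec("ALL_EXC", "ASD", N = 12L, iapp = read_iapp(f),
                        settings = tiny_settings())
  expect_identical(sort(as.numeric(build_scenario(spec)$config$Iapp)),
                   sort(as.numeric(x)))
})

test_that("invalid scenarios report all violations", {
  expect_error(scenario_spec(N = 0L, settings = tiny_settings()), "positive")
  expect_error(
    scenario_spec(N = 10L, precision = hfpp(50L), summation = "REPRODUCIBLE",
                  settings = tiny_settings()),
    "binary64")
  expect_error(network_configuration(3, "ALL_EXC", c("0", "7", "0"), "NAIVE"),
               "\\[-10, 5\\]")
})
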