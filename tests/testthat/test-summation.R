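# Accumulation strategies: order sensitivity, compensation, and the
# correctly rounded order-invariant sum.

ex_fwd <- c(0.1, 0.1, 0.1, -0.3)
ex_rev <- c(-0.3, 0.1, 0.1, 0.1)

test_that("naive accumulation is order-sensitive in the documented way", {
  expect_identical(sum_ordered(ex_fwd, "NAIVE"), 5.551115123125783e-17)
  expect_identical(sum_ordered(ex_rev, "NAIVE"), 2.7755575615628914e-17)
  # re-association: pre-round the group (0.1 - 0.3), then accumulate
  grouped <- c(0.1, 0.1, 0.1 + (-0.3))
  expect_identical(sum_ordered(grouped, "NAIVE"), 2.7755575615628914e-17)
})

test_that("Kahan compensation fixes one ordering but not the other", {
  expect_identical(sum_ordered(ex_fwd, "KAHAN"), 0)
  expect_identical(sum_ordered(ex_rev, "KAHAN"), 2.7755575615628914e-17)
})

test_that("the reproducible sum is the rounding of the exact sum, any order", {
  expect_identical(sum_reproducible(ex_fwd), 2.7755575615628914e-17)
  expect_identical(sum_reproducible(ex_rev), 2.7755575615628914e-17)
  # every permutation of the four-element example
  perms <- list(c(1,2,3,4), c(4,3,2,1), c(2,4,1,3), c(3,1,4,2), c(1,4,2,3))
  for (p in perms)
    expect_identical(sum_reproducible(ex_fwd[p]), 2.7755575615628914e-17)
})

test_that("empty and singleton sums are exact", {
  expect_identical(sum_ordered(numeric(0), "NAIVE"), 0)
  expect_identical(sum_ordered(numeric(0), "KAHAN"), 0)
  expect_identical(sum_reproducible(numeric(0)), 0)
  x <- 0.1 + 0.2
  expect_identical(sum_reproducible(x), x)
})

test_that("all strategies are exact on small-integer vectors", {
  set.seed(11)
  for (i in 1:20) {
    v <- as.numeric(sample(-1000:1000, sample(1:100, 1), replace = TRUE))
    s <- sum(v)
    expect_identical(sum_ordered(v, "NAIVE"), s)
    expect_identical(sum_ordered(v, "KAHAN"), s)
    expect_identical(sum_reproducible(v), s)
  }
})

test_that("reproducible sum matches the exact decimal oracle and is
           permutation-invariant on mixed-magnitude vectors", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(1:60, 1)
    v <- runif(n, -1, 1) * 10^runif(n, -10, 10)
    r <- sum_reproducible(v)
    expect_identical(r, sum_exact_decimal(v))
    for (k in 1:5)
      expect_identical(sum_reproducible(v[sample.int(n)]), r)
  }
})

test_that("extreme magnitudes including subnormals are summed exactly", {
  v <- c(1e308, 5e-324, -1e308, 3e-324, 1e-300)
  expect_identical(sum_reproducible(v), sum_exact_decimal(v))
  expect_identical(sum_reproducible(c(5e-324, 5e-324)), 1e-323)
})

test_that("high-precision vectors use ordered accumulation only", {
  xs <- lapply(c("0.1", "0.1", "0.1", "-0.3"),
               make_scalar, spec = hfpp(30L))
  s <- sum_ordered(xs, "NAIVE")
  # one tenth is exact in decimal, so the decimal sum is exactly zero
  expect_identical(to_decimal_string(s, 1), "0")
  expect_error(sum_reproducible(xs), "binary64")
})
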