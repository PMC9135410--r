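# Scalar backends, literal initialization, and exact decimal expansions.

test_that("literals materialize exactly per backend", {
  # powers of two are exact in binary64
  expect_identical(as.numeric(make_scalar("0.5")), 0.5)
  # one tenth is exact in the decimal backend but not in binary64
  s <- make_scalar("0.1", hfpp(100L))
  expect_identical(to_decimal_string(s, 2, "truncate"), "0.10")
  d <- make_scalar("0.1")
  expect_identical(to_decimal_string(d, 20), "0.10000000000000000555")
  # the binary64 nearest 3.6, expanded to 22 significant digits
  expect_identical(to_decimal_string(make_scalar("3.6"), 22),
                   "3.600000000000000088818")
  # a literal that is not representable gets the documented neighbour
  expect_identical(to_decimal_string(make_scalar("0.036"), 20),
                   "0.035999999999999997280")
  # dividing materialized literals: 3.6 / 100 in binary64
  g <- make_scalar("3.6") / make_scalar("100.00000000000")
  expect_identical(to_decimal_string(g, 20), "0.036000000000000004219")
})

test_that("exact binary64 expansions are exact, not shortest round-trip", {
  expect_identical(to_decimal_string(0.1, 40),
                   "0.1000000000000000055511151231257827021182")
  expect_identical(to_decimal_string(0.5, 3), "0.500")
  # full exact expansion of the double nearest 0.1 terminates
  full <- to_decimal_string(0.1, 55, "truncate")
  expect_identical(full,
    "0.1000000000000000055511151231257827021181583404541015625")
})

test_that("binary32 representation queries widen losslessly", {
  f <- nearest_binary32("0.1")
  expect_identical(to_decimal_string(f, 20), "0.10000000149011611938")
  # 13421773 / 2^27 exactly
  expect_identical(to_decimal_string(f, 27, "truncate"),
                   "0.100000001490116119384765625")
  expect_identical(as.numeric(nearest_binary32("1.0")), 1)
  expect_identical(as.numeric(nearest_binary32("0.25")), 0.25)
  expect_error(nearest_binary32("1e60"), "binary32")
})

test_that("17-digit decimal strings round-trip binary64 bit for bit", {
  set.seed(7)
  xs <- c(runif(100, -1, 1) * 10^runif(100, -30, 30), 0.1, -3.6, 2^-40,
          .Machine$double.xmin, .Machine$double.eps)
  for (x in xs) {
    back <- as.numeric(make_scalar(to_decimal_string(x, 17)))
    expect_identical(back, x)
  }
})

test_that("HFPP literals round-trip exactly up to trailing zeros", {
  set.seed(8)
  for (i in 1:50) {
    nd <- sample(1:40, 1)
    lit <- paste0("0.", paste(sample(0:9, nd, replace = TRUE), collapse = ""))
    lit <- sub("0+$", "", lit)
    if (lit == "0.") lit <- "0.5"
    s <- make_scalar(lit, hfpp(40L))
    nsig <- nchar(sub("^0\\.0*", "", lit))
    got <- to_decimal_string(s, nsig, "truncate")
    expect_identical(sub("0+$", "", got), sub("0+$", "", lit))
  }
})

test_that("the decimal backend dominates binary64 on random literals", {
  set.seed(9)
  for (i in 1:300) {
    lit <- sprintf("%.*g", sample(5:17, 1),
                   runif(1, -1, 1) * 10^sample(-20:20, 1))
    hi <- as.numeric(make_scalar(lit, hfpp(100L)))
    lo <- as.numeric(make_scalar(lit))
    if (hi != 0) expect_lt(abs(hi - lo) / abs(hi), 1e-15)
  }
})

test_that("scalar arithmetic respects backend discipline", {
  a <- make_scalar("0.1", hfpp(30L))
  b <- make_scalar("0.3", hfpp(30L))
  expect_identical(to_decimal_string(a + b, 2, "truncate"), "0.40")
  expect_identical(to_decimal_string(a * b, 2, "truncate"), "0.030")
  d <- make_scalar("0.1")
  expect_error(a + d, "backend")
  expect_error(a + 0.1, "high-precision")
  expect_error(a + make_scalar("0.1", hfpp(40L)), "backend")
  # DFPP scalars interoperate with bare numerics
  expect_identical(as.numeric(d + 0.2), 0.1 + 0.2)
  # comparison operators
  expect_true(a < b)
  expect_true(a == make_scalar("0.1000", hfpp(30L)))
})

test_that("malformed literals raise errors naming the text", {
  expect_error(make_scalar("1.2.3"), "1\\.2\\.3")
  expect_error(make_scalar("abc", hfpp(20L)), "abc")
  expect_error(make_scalar("1e", hfpp(20L)), "1e")
})

test_that("hp_exp is exact at zero and accurate to the working precision", {
  one <- hp_exp(make_scalar("0", hfpp(40L)))
  expect_identical(to_decimal_string(one, 1), "1")
  # e to 30 digits, against an independently computed constant
  e30 <- hp_exp(make_scalar("1", hfpp(30L)))
  expect_identical(to_decimal_string(e30, 30), "2.71828182845904523536028747135")
  # negative argument and argument reduction through e^n
  em <- hp_exp(make_scalar("-11.3", hfpp(30L)))
  expect_identical(to_decimal_string(em, 30),
                   "0.0000123729242617882305171267578151")
  big <- hp_exp(make_scalar("16", hfpp(30L)))
  expect_identical(to_decimal_string(big, 30), "8886110.52050787263676302374078")
  # identity: exp(x) * exp(-x) = 1 to within one unit in the last place
  set.seed(10)
  for (x in sprintf("%.6f", runif(5, 0.1, 12))) {
    p <- hp_exp(make_scalar(x, hfpp(30L))) *
      hp_exp(make_scalar(paste0("-", x), hfpp(30L)))
    dev <- p - make_scalar("1", hfpp(30L))
    expect_lt(abs(as.numeric(dev)), 1e-28)
  }
  # DFPP delegates to the platform exponential
  expect_identical(as.numeric(hp_exp(make_scalar("2.5"))), exp(2.5))
})

test_that("hp_pow uses the fixed multiplication chain", {
  expect_identical(hp_pow(2, 4), 16)
  expect_identical(hp_pow(0, 3), 0)
  expect_identical(hp_pow(0.3, 4), ((0.3 * 0.3) * 0.3) * 0.3)
  s <- hp_pow(make_scalar("0.3", hfpp(30L)), 4)
  expect_identical(to_decimal_string(s, 4, "truncate"), "0.008100")
  expect_error(hp_pow(2, 5), "1\\.\\.4")
})
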