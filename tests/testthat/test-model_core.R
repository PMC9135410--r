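# Rate functions, currents, conductance pools, and the state derivative.
# High-precision reference values were computed with an independent
# arbitrary-precision evaluation of the same closed forms (50-digit
# arithmetic) and frozen here.

test_that("alpha_n matches the high-precision reference", {
  expect_equal(rate_alpha_n(0), 0.058197670686932642438500200510901,
               tolerance = 1e-15)
  expect_equal(rate_alpha_n(20), 0.1581976706869326424385002005109,
               tolerance = 1e-15)
  expect_equal(rate_alpha_n(-35.75), 0.0047642334896333515992092534620558,
               tolerance = 1e-15)
  # the same evaluation under the decimal backend agrees to ~28 digits
  a <- rate_alpha_n(make_scalar("0", hfpp(30L)))
  dev <- a - make_scalar("0.058197670686932642438500200510901", hfpp(30L))
  expect_lt(abs(as.numeric(dev)), 1e-28)
})

test_that("alpha_n raises at its removable singularity unless told otherwise", {
  expect_error(rate_alpha_n(10), "singularity")
  expect_identical(rate_alpha_n(10, "limit"), 0.1)
  expect_error(rate_alpha_n(make_scalar("10", hfpp(30L))), "singularity")
  lim <- rate_alpha_n(make_scalar("10", hfpp(30L)), "limit")
  expect_identical(to_decimal_string(lim, 2, "truncate"), "0.10")
})

test_that("beta_n matches the high-precision reference", {
  expect_identical(rate_beta_n(0), 0.125)
  expect_equal(rate_beta_n(80), 0.045984930146430290199440471270183,
               tolerance = 1e-15)
  expect_equal(rate_beta_n(-80), 0.33978522855738065442003593391908,
               tolerance = 1e-15)
  expect_equal(rate_beta_n(13.5), 0.10559000712562293064865311497029,
               tolerance = 1e-15)
})

test_that("m_inf matches the reference, stays in (0,1), and is monotone", {
  expect_equal(m_inf(0), 0.052932485257249574964888124285333,
               tolerance = 1e-15)
  expect_equal(m_inf(50), 0.91632452263968966412237673014322,
               tolerance = 1e-15)
  expect_equal(m_inf(-12.25), 0.011516689848959132219920866336646,
               tolerance = 1e-15)
  expect_error(m_inf(25), "singularity")
  expect_identical(m_inf(25, "limit"), 1 / (1 + 4 * exp(-25 / 18)))
  grid <- seq(-20, 120, by = 1)
  vals <- m_inf(grid, "limit")
  expect_true(all(vals > 0 & vals < 1))
  expect_true(all(diff(vals) >= 0))
})

test_that("the release gate is a sigmoid anchored at the threshold", {
  expect_identical(pi_release(40), 0.5)  # V = V_th, exp(0) exact
  expect_equal(pi_release(40 + 20 * 6.5), 0.99999999793884638180979641856914,
               tolerance = 1e-15)
  expect_lt(pi_release(-1e4), 1e-200)
  expect_error(pi_release(0, k_v = 0), "nonzero")
})

test_that("ionic currents vanish at their reversal points", {
  p <- model_parameters()
  cur <- ionic_currents(115, 0.3, p)
  expect_identical(cur$I_Na, 0)
  cur <- ionic_currents(3, 0, p)
  expect_identical(cur$I_K, 0)
  cur <- ionic_currents(-10.6, 0.3, p)
  expect_identical(cur$I_l, 0)
})

test_that("synaptic conductances follow the pool-sum-minus-self rule", {
  p <- model_parameters()
  # two excitatory neurons, a = 0.5, s = 1: g_e = (3.6/2) * (1.0 - 0.5)
  cfg <- network_configuration(2, "ALL_EXC", c("0", "0"), "NAIVE")
  g <- synaptic_conductances(list(a = c(0.5, 0.5), s = c(1, 1)), cfg, p)
  expect_equal(g$g_e, c(0.9, 0.9), tolerance = 1e-15)
  expect_identical(g$g_i, c(0, 0))
  # ten neurons with unit products: every neuron sees (3.6/10) * 9
  cfg10 <- network_configuration(10, "ALL_EXC", rep("0", 10), "NAIVE")
  g10 <- synaptic_conductances(list(a = rep(1, 10), s = rep(1, 10)), cfg10, p)
  expect_equal(g10$g_e, rep(0.36 * 9, 10), tolerance = 1e-14)
  # silent network
  g0 <- synaptic_conductances(list(a = rep(0, 10), s = rep(1, 10)), cfg10, p)
  expect_identical(g0$g_e, rep(0, 10))
})

test_that("pool split only re-associates the sum (exact-arithmetic identity)", {
  # dyadic states and a dyadic gbar/N make every sum and product exact, so
  # the identity g_e + g_i (split) == g_e (single pool) holds bitwise
  set.seed(13)
  p <- model_parameters(gbar_syn = "4")
  N <- 8L
  a <- sample(0:4096, N) / 4096
  s <- sample(0:4096, N) / 4096
  iapp <- rep("0", N)
  cfg1 <- network_configuration(N, "ALL_EXC", iapp, "REPRODUCIBLE")
  cfg2 <- network_configuration(N, "SPLIT_80_20", iapp, "REPRODUCIBLE")
  g1 <- synaptic_conductances(list(a = a, s = s), cfg1, p)
  g2 <- synaptic_conductances(list(a = a, s = s), cfg2, p)
  expect_identical(g2$g_e + g2$g_i, g1$g_e)
})

test_that("state derivative honours its stationarity identities", {
  p <- model_parameters()
  N <- 4L
  cfg <- network_configuration(N, "ALL_EXC", rep("0", N), "NAIVE")
  V <- c(-5, 0, 3.5, 7)
  n_ss <- rate_alpha_n(V) / (rate_alpha_n(V) + rate_beta_n(V))
  st <- list(V = V, n = n_ss, a = rep(0, N), s = rep(1, N))
  d <- state_derivatives(st, cfg, p)
  expect_true(all(abs(d$dn) < 1e-16))         # n at its steady state
  expect_true(all(abs(d$da) < 1e-2))          # a = 0 with Pi(V) small
  expect_true(all(abs(d$ds) < 1e-2))          # s = 1, recovery term zero
  # finite everywhere on the nominal band
  expect_true(all(is.finite(unlist(d))))
})

test_that("the reference derivative and the compiled engine agree bitwise", {
  set.seed(14)
  p <- model_parameters()
  for (split in c("ALL_EXC", "SPLIT_80_20")) {
    for (summ in c("NAIVE", "KAHAN", "REPRODUCIBLE")) {
      N <- 10L
      iapp <- generate_iapp(3, N)
      cfg <- network_configuration(N, split, iapp, summ)
      st <- list(V = runif(N, -20, 100), n = runif(N, 0.1, 0.7),
                 a = runif(N), s = runif(N))
      d1 <- state_derivatives(st, cfg, p)
      d2 <- hhrepro:::cpp_deriv_f64(unclass(p), cfg$Iapp, cfg$is_exc,
                                    hhrepro:::sum_kind_code(summ), FALSE, 0L,
                                    st$V, st$n, st$a, st$s)
      expect_identical(d1$dV, d2$dV)
      expect_identical(d1$dn, d2$dn)
      expect_identical(d1$da, d2$da)
      expect_identical(d1$ds, d2$ds)
    }
  }
})
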