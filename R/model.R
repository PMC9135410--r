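#' Biophysical parameters of the depressing Hodgkin-Huxley network
#'
#' All constants of the membrane, gating, and synaptic equations, stored as
#' decimal literal strings so that both precision backends materialize them
#' from the same text (never through a binary64 intermediate). Defaults are
#' the published parameter set of the model: conductances in mS/cm^2,
#' potentials in mV, rates in 1/ms, currents in uA/cm^2.
#'
#' Two constants are not fixed by the published table and are documented
#' package choices: the membrane capacitance `C` (1 uF/cm^2, the standard
#' squid-axon value) and the synaptic release slope `k_v` (6.5 mV, selected
#' so the network expresses the episodic activity rhythm; see the methods
#' vignette for the identification procedure).
#'
#' @param ... Named overrides, as decimal literal strings (numeric values are
#'   accepted and formatted to 17 significant digits).
#' @return An object of class `hh_parameters`: a named list of literals.
#' @examples
#' p <- model_parameters()
#' p$gbar_syn
#' model_parameters(k_v = "5")$k_v
#' @export
model_parameters <- function(...) {
  defaults <- list(
    C = "1",            # membrane capacitance, uF/cm^2 (not in the published table)
    g_l = "0.1",        # leak conductance, mS/cm^2
    V_l = "-10.6",      # leak reversal potential, mV
    g_Na = "36",        # sodium conductance, mS/cm^2
    V_Na = "115",       # sodium reversal potential, mV
    g_K = "12",         # potassium conductance, mS/cm^2
    V_K = "-12",        # potassium reversal potential, mV
    gbar_syn = "3.6",   # maximal synaptic conductance, mS/cm^2
    V_exc = "70",       # excitatory reversal potential, mV
    V_inh = "70",       # inhibitory reversal potential, mV (same value: "fake" inhibition)
    alpha_a = "1",      # synaptic activation rate, 1/ms
    beta_a = "0.1",     # synaptic decay rate, 1/ms
    alpha_s = "0.0015", # synaptic recovery rate, 1/ms
    beta_s = "0.12",    # synaptic depression rate, 1/ms
    V_th = "40",        # release threshold, mV
    k_v = "6.5"         # release slope, mV (not in the published table)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(ov)) {
      v <- ov[[nm]]
      if (is.numeric(v)) v <- sprintf("%.17g", v)
      cpp_strtod_strict(v)  # validates the literal
      defaults[[nm]] <- v
    }
  }
  if (cpp_strtod_strict(defaults$C) <= 0)
    stop("C must be positive", call. = FALSE)
  if (cpp_strtod_strict(defaults$k_v) == 0)
    stop("k_v must be nonzero", call. = FALSE)
  structure(defaults, class = "hh_parameters")
}

#' @export
print.hh_parameters <- function(x, ...) {
  cat("<hh_parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %s\n", nm, x[[nm]]))
  invisible(x)
}

# generic numeric helpers so the rate functions run on doubles and scalars
hh_lit <- function(s, template) {
  if (inherits(template, "hh_scalar")) make_scalar(s, template$spec) else
    cpp_strtod_strict(s)
}
hh_exp_g <- function(x) if (inherits(x, "hh_scalar")) hp_exp(x) else exp(x)

#' Potassium activation rate alpha_n
#'
#' `alpha_n(V) = 0.01 (10 - V) / (e^{0.1 (10 - V)} - 1)`, evaluated in
#' exactly that operation order. V = 10 mV is a removable singularity (0/0
#' with limit 0.1): by default evaluation there raises an error so the hazard
#' stays visible; `singularity = "limit"` substitutes the analytic limit.
#'
#' @param V Membrane potential, mV (numeric vector or one `hh_scalar`).
#' @param singularity `"error"` or `"limit"`.
#' @return Rate in 1/ms, same type as `V`.
#' @export
rate_alpha_n <- function(V, singularity = c("error", "limit")) {
  singularity <- match.arg(singularity)
  if (inherits(V, "hh_scalar")) {
    ten <- hh_lit("10.0", V)
    if (V == ten) {
      if (singularity == "error")
        stop("removable singularity in alpha_n at V = 10; ",
             "use singularity = \"limit\"", call. = FALSE)
      return(hh_lit("0.1", V))
    }
    t <- ten - V
    return((hh_lit("0.01", V) * t) / (hp_exp(hh_lit("0.1", V) * t) - hh_lit("1.0", V)))
  }
  if (any(V == 10)) {
    if (singularity == "error")
      stop("removable singularity in alpha_n at V = 10; ",
           "use singularity = \"limit\"", call. = FALSE)
    out <- numeric(length(V))
    out[V == 10] <- 0.1
    vv <- V[V != 10]
    out[V != 10] <- 0.01 * (10 - vv) / (exp(0.1 * (10 - vv)) - 1)
    return(out)
  }
  0.01 * (10 - V) / (exp(0.1 * (10 - V)) - 1)
}

#' Potassium deactivation rate beta_n
#'
#' `beta_n(V) = 0.125 e^{-V/80}`.
#'
#' @inheritParams rate_alpha_n
#' @return Rate in 1/ms.
#' @export
rate_beta_n <- function(V) {
  if (inherits(V, "hh_scalar"))
    return(hh_lit("0.125", V) * hp_exp((-V) / hh_lit("80", V)))
  0.125 * exp(-V / 80)
}

#' Instantaneous sodium activation m_inf
#'
#' The sodium current assumes instantaneous activation:
#' `m_inf(V) = alpha_m / (alpha_m + beta_m)` with the classic squid-axon
#' rates in the rest-at-0-mV convention,
#' `alpha_m(V) = 0.1 (25 - V) / (e^{0.1 (25 - V)} - 1)` and
#' `beta_m(V) = 4 e^{-V/18}`. V = 25 mV is a removable singularity of
#' `alpha_m` (limit 1).
#'
#' @inheritParams rate_alpha_n
#' @return Dimensionless activation in (0, 1).
#' @export
m_inf <- function(V, singularity = c("error", "limit")) {
  singularity <- match.arg(singularity)
  if (inherits(V, "hh_scalar")) {
    tf <- hh_lit("25.0", V)
    am <- if (V == tf) {
      if (singularity == "error")
        stop("removable singularity in alpha_m at V = 25; ",
             "use singularity = \"limit\"", call. = FALSE)
      hh_lit("1.0", V)
    } else {
      t <- tf - V
      (hh_lit("0.1", V) * t) / (hp_exp(hh_lit("0.1", V) * t) - hh_lit("1.0", V))
    }
    bm <- hh_lit("4", V) * hp_exp((-V) / hh_lit("18", V))
    return(am / (am + bm))
  }
  am <- numeric(length(V))
  if (any(V == 25)) {
    if (singularity == "error")
      stop("removable singularity in alpha_m at V = 25; ",
           "use singularity = \"limit\"", call. = FALSE)
    am[V == 25] <- 1
  }
  vv <- V[V != 25]
  am[V != 25] <- 0.1 * (25 - vv) / (exp(0.1 * (25 - vv)) - 1)
  bm <- 4 * exp(-V / 18)
  am / (am + bm)
}

#' Synaptic release gate
#'
#' `Pi(V) = 1 / (1 + e^{(V_th - V)/k_v})`: the sigmoidal fraction of maximal
#' transmitter release as the presynaptic potential depolarizes above the
#' release threshold.
#'
#' @inheritParams rate_alpha_n
#' @param V_th Release threshold, mV.
#' @param k_v Release slope, mV (nonzero).
#' @return Dimensionless gate in (0, 1).
#' @export
pi_release <- function(V, V_th = 40, k_v = 6.5) {
  if (inherits(V, "hh_scalar")) {
    vth <- if (inherits(V_th, "hh_scalar")) V_th else hh_lit(sprintf("%.17g", V_th), V)
    kv <- if (inherits(k_v, "hh_scalar")) k_v else hh_lit(sprintf("%.17g", k_v), V)
    one <- hh_lit("1.0", V)
    return(one / (one + hp_exp((vth - V) / kv)))
  }
  if (any(k_v == 0)) stop("k_v must be nonzero", call. = FALSE)
  1 / (1 + exp((V_th - V) / k_v))
}

params_num <- function(params) {
  stopifnot(inherits(params, "hh_parameters"))
  vapply(unclass(params), cpp_strtod_strict, numeric(1))
}

#' Ionic membrane currents
#'
#' Sodium (instantaneous activation, inactivation approximated by `0.8 - n`),
#' delayed-rectifier potassium, and leak currents:
#' `I_Na = g_Na m_inf^3(V) (0.8 - n) (V - V_Na)`,
#' `I_K = g_K n^4 (V - V_K)`, `I_l = g_l (V - V_l)`, with the integer powers
#' computed by the fixed multiplication chain of [hp_pow()].
#'
#' @param V,n Membrane potential (mV) and K-gate fraction, numeric vectors.
#' @param params An [model_parameters()] object.
#' @param singularity Passed to [m_inf()].
#' @return A list with numeric vectors `I_Na`, `I_K`, `I_l` (uA/cm^2).
#' @export
ionic_currents <- function(V, n, params = model_parameters(),
                           singularity = c("error", "limit")) {
  singularity <- match.arg(singularity)
  p <- params_num(params)
  m <- m_inf(V, singularity)
  I_Na <- p[["g_Na"]] * hp_pow(m, 3) * (0.8 - n) * (V - p[["V_Na"]])
  I_K <- p[["g_K"]] * hp_pow(n, 4) * (V - p[["V_K"]])
  I_l <- p[["g_l"]] * (V - p[["V_l"]])
  list(I_Na = I_Na, I_K = I_K, I_l = I_l)
}

#' Network configuration: pools, applied currents, accumulation strategy
#'
#' @param N Neuron count.
#' @param split `"ALL_EXC"` (every neuron excitatory) or `"SPLIT_80_20"`
#'   (first 80 percent of indices excitatory, remainder labelled inhibitory;
#'   with the default `V_exc = V_inh` the "inhibitory" pool still acts
#'   excitatorily -- the split only changes how the conductance sum is
#'   associated into two partial sums).
#' @param Iapp Applied currents, uA/cm^2: a character vector of decimal
#'   literals (one per neuron) or a numeric vector (formatted to 17
#'   significant digits). Every value must lie in `[-10, 5]`.
#' @param summation `"NAIVE"`, `"KAHAN"`, or `"REPRODUCIBLE"`: the strategy
#'   used for every cross-neuron sum (conductance pools and population
#'   averages), always over terms in ascending neuron index.
#' @return An object of class `hh_config`.
#' @export
network_configuration <- function(N, split = c("ALL_EXC", "SPLIT_80_20"),
                                  Iapp,
                                  summation = c("NAIVE", "KAHAN", "REPRODUCIBLE")) {
  split <- match.arg(split)
  summation <- match.arg(summation)
  N <- as.integer(N)
  problems <- character(0)
  if (is.na(N) || N < 1L) problems <- c(problems, "N must be a positive integer")
  if (is.numeric(Iapp)) Iapp <- sprintf("%.16e", Iapp)
  if (!is.character(Iapp)) problems <- c(problems, "Iapp must be character or numeric")
  if (is.character(Iapp) && length(Iapp) != N)
    problems <- c(problems, sprintf("Iapp has length %d but N = %d", length(Iapp), N))
  vals <- suppressWarnings(as.numeric(Iapp))
  if (any(is.na(vals)) || any(vals < -10) || any(vals > 5))
    problems <- c(problems, "every Iapp value must lie in [-10, 5]")
  if (length(problems))
    stop("invalid network configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  Ne <- if (split == "ALL_EXC") N else as.integer(round(N * 0.8))
  Ni <- N - Ne
  structure(list(N = N, split = split, Ne = Ne, Ni = Ni,
                 is_exc = c(rep(TRUE, Ne), rep(FALSE, Ni)),
                 Iapp = Iapp, summation = summation),
            class = "hh_config")
}

#' @export
print.hh_config <- function(x, ...) {
  cat(sprintf("<hh_config> N=%d (%s: Ne=%d, Ni=%d), summation=%s\n",
              x$N, x$split, x$Ne, x$Ni, x$summation))
  invisible(x)
}

sum_by_strategy <- function(x, strategy) {
  switch(strategy,
         NAIVE = sum_ordered(x, "NAIVE"),
         KAHAN = sum_ordered(x, "KAHAN"),
         REPRODUCIBLE = sum_reproducible(x))
}

#' Presynaptic conductances
#'
#' For each neuron `k`, the excitatory and inhibitory synaptic conductances
#' `g_e = (gbar_syn/N) (sum_{j in exc} a_j s_j - [a_k s_k])` and analogously
#' `g_i` over the inhibitory pool, where the own term is subtracted only from
#' the pool containing neuron `k` (all-to-all coupling without an autapse).
#' Each pool sum runs over terms in ascending neuron index under the
#' configured summation strategy; the product `a_j s_j` is formed once per
#' neuron and reused by both pools. Under `ALL_EXC` the inhibitory
#' conductance is identically zero.
#'
#' @param state A list with numeric vectors `a` and `s` of length `N`.
#' @param config An [network_configuration()].
#' @param params An [model_parameters()].
#' @return A list with numeric vectors `g_e`, `g_i` (mS/cm^2).
#' @export
synaptic_conductances <- function(state, config, params = model_parameters()) {
  stopifnot(inherits(config, "hh_config"))
  p <- params_num(params)
  N <- config$N
  a <- state$a
  s <- state$s
  stopifnot(length(a) == N, length(s) == N)
  gsyn_over_N <- p[["gbar_syn"]] / N
  as_ <- a * s
  Se <- sum_by_strategy(as_[config$is_exc], config$summation)
  Si <- if (config$Ni > 0) sum_by_strategy(as_[!config$is_exc], config$summation) else 0
  g_e <- ifelse(config$is_exc, gsyn_over_N * (Se - as_), gsyn_over_N * Se)
  g_i <- ifelse(config$is_exc, gsyn_over_N * Si, gsyn_over_N * (Si - as_))
  if (config$Ni == 0) g_i <- rep(0, N)
  list(g_e = g_e, g_i = g_i)
}

#' Full state derivative of the network
#'
#' The right-hand side of the model: for every neuron,
#' `C dV/dt = -[I_Na + I_K + I_l + g_e (V - V_exc) + g_i (V - V_inh) - Iapp]`,
#' `dn/dt = alpha_n(V)(1 - n) - beta_n(V) n`,
#' `da/dt = Pi(V) alpha_a (1 - a) - beta_a a`, and
#' `ds/dt = alpha_s (1 - s) - Pi(V) beta_s s`, evaluated in exactly this
#' order. This is the reference (binary64) implementation against which the
#' compiled integrator is checked bit for bit.
#'
#' @param state List with numeric vectors `V`, `n`, `a`, `s` of length `N`.
#' @param config An [network_configuration()].
#' @param params An [model_parameters()].
#' @param singularity `"error"` or `"limit"` for the removable rate
#'   singularities at V = 10 and V = 25.
#' @return A list with numeric vectors `dV`, `dn`, `da`, `ds`.
#' @export
state_derivatives <- function(state, config, params = model_parameters(),
                              singularity = c("error", "limit")) {
  singularity <- match.arg(singularity)
  p <- params_num(params)
  V <- state$V; n <- state$n; a <- state$a; s <- state$s
  g <- synaptic_conductances(state, config, params)
  an <- rate_alpha_n(V, singularity)
  bn <- rate_beta_n(V)
  cur <- ionic_currents(V, n, params, singularity)
  Iapp <- vapply(config$Iapp, cpp_strtod_strict, numeric(1), USE.NAMES = FALSE)
  Isyn_e <- g$g_e * (V - p[["V_exc"]])
  Isyn_i <- g$g_i * (V - p[["V_inh"]])
  dV <- -(cur$I_Na + cur$I_K + cur$I_l + Isyn_e + Isyn_i - Iapp) / p[["C"]]
  dn <- an * (1 - n) - bn * n
  Pi <- pi_release(V, p[["V_th"]], p[["k_v"]])
  da <- Pi * p[["alpha_a"]] * (1 - a) - p[["beta_a"]] * a
  ds <- p[["alpha_s"]] * (1 - s) - Pi * p[["beta_s"]] * s
  list(dV = dV, dn = dn, da = da, ds = ds)
}
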