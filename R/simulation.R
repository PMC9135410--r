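#' Integration settings
#'
#' @param dt Time step in ms, as a decimal literal string (default `"0.01"`)
#'   so both backends materialize the identical quantity.
#' @param duration Simulated time in ms; must be a whole number of steps
#'   (checked to within 0.5 ulp of the step count).
#' @param record_stride Record every this many steps (>= 1).
#' @return An object of class `hh_settings` carrying `dt` (literal),
#'   `duration`, `record_stride`, and the derived integer `n_steps`.
#' @export
simulation_settings <- function(dt = "0.01", duration = 8000, record_stride = 1L) {
  if (is.numeric(dt)) dt <- sprintf("%.17g", dt)
  dtv <- cpp_strtod_strict(dt)
  if (!is.finite(dtv) || dtv <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0)
    stop("duration must be a single non-negative number (ms)", call. = FALSE)
  n_steps <- round(duration / dtv)
  if (abs(n_steps * dtv - duration) > 0.5 * .Machine$double.eps *
        max(1, abs(duration)) * n_steps + 1e-9)
    stop("duration must be an integer multiple of dt", call. = FALSE)
  record_stride <- as.integer(record_stride)
  if (is.na(record_stride) || record_stride < 1L)
    stop("record_stride must be >= 1", call. = FALSE)
  structure(list(dt = dt, duration = duration, record_stride = record_stride,
                 n_steps = as.integer(n_steps)),
            class = "hh_settings")
}

#' One fixed-step fourth-order Runge-Kutta update with pinned operation order
#'
#' Advances `y' = f(t, y)` by one step of the classical RK4 scheme with every
#' floating-point operation in a fixed order and association:
#' `u1 = y + dt*k1/2` (per component, computed as `(dt*k1_i)/2`),
#' `u2 = y + dt*k2/2`, `u3 = y + dt*k3`, and
#' `y* = y + dt*(k1 + 2*k2 + 2*k3 + k4)/6` with the bracket accumulated left
#' to right. Freezing this order is what lets two implementations of the
#' same solver agree bit for bit.
#'
#' @param f Derivative function `f(t, y)` returning a vector like `y`.
#' @param t Current time.
#' @param y Numeric state vector.
#' @param dt Step size.
#' @return The state after one step.
#' @examples
#' # linear decay: one step reproduces the degree-4 Taylor polynomial
#' rk4_step(function(t, y) -y, 0, 1, 0.1)  # 1 - h + h^2/2 - h^3/6 + h^4/24
#' @export
rk4_step <- function(f, t, y, dt) {
  k1 <- f(t, y)
  u1 <- y + dt * k1 / 2
  k2 <- f(t + dt / 2, u1)
  u2 <- y + dt * k2 / 2
  k3 <- f(t + dt / 2, u2)
  u3 <- y + dt * k3
  k4 <- f(t + dt, u3)
  y + dt * (((k1 + 2 * k2) + 2 * k3) + k4) / 6
}

default_initial_conditions <- function() {
  list(V = "0", n = "0.3", a = "0", s = "1")
}

check_initial_conditions <- function(ic, N) {
  if (!is.list(ic) || !all(c("V", "n", "a", "s") %in% names(ic)))
    stop("initial_conditions must be a list with components V, n, a, s",
         call. = FALSE)
  for (nm in c("V", "n", "a", "s")) {
    v <- ic[[nm]]
    if (is.numeric(v)) v <- sprintf("%.17g", v)
    if (!is.character(v) || !(length(v) %in% c(1L, N)))
      stop(sprintf("initial condition '%s' must have length 1 or N", nm),
           call. = FALSE)
    vapply(v, cpp_strtod_strict, numeric(1))
    ic[[nm]] <- v
  }
  ic[c("V", "n", "a", "s")]
}

sum_kind_code <- function(summation) {
  match(summation, c("NAIVE", "KAHAN", "REPRODUCIBLE")) - 1L
}

#' Run a full network simulation
#'
#' Integrates the network with the deterministic fixed-step RK4 scheme under
#' the requested precision backend, recording the population averages
#' `<A> = (1/N) sum_j a_j` and `<S> = (1/N) sum_j s_j` (each population sum
#' computed with the configured summation strategy, the same one used for
#' the conductance pools). Sample times are fresh products `i * dt`, never
#' an accumulated time variable. Two runs with identical inputs on the same
#' machine produce bitwise-identical traces.
#'
#' @param params [model_parameters()].
#' @param config [network_configuration()].
#' @param settings [simulation_settings()].
#' @param precision [precision_spec()]; HFPP runs additionally carry every
#'   recorded average as a full-precision decimal string.
#' @param initial_conditions List of literals for `V`, `n`, `a`, `s` (length
#'   1 or N each). Defaults: V = "0", n = "0.3", a = "0", s = "1" -- a
#'   near-rest start with fully recovered synapses, exactly representable in
#'   both backends.
#' @param singularity `"error"` aborts at the removable rate singularities
#'   (V exactly 10 or 25 mV); `"limit"` substitutes the analytic limits.
#' @param unified_accumulation When `TRUE` (requires `V_exc == V_inh`), both
#'   pools are accumulated as one order-invariant sum before the split is
#'   applied, making the excitatory/inhibitory association irrelevant to the
#'   arithmetic. Off by default because it changes the model's arithmetic
#'   path; see the methods vignette.
#' @return An object of class `hh_trace`: `times` (ms), `A`, `S` (doubles),
#'   for HFPP also `A_str`, `S_str` (decimal strings), plus `meta` with the
#'   full provenance.
#' @export
run_simulation <- function(params, config, settings,
                           precision = precision_spec("DFPP"),
                           initial_conditions = default_initial_conditions(),
                           singularity = c("error", "limit"),
                           unified_accumulation = FALSE) {
  stopifnot(inherits(params, "hh_parameters"), inherits(config, "hh_config"),
            inherits(settings, "hh_settings"), inherits(precision, "hh_precision"))
  singularity <- match.arg(singularity)
  ic <- check_initial_conditions(initial_conditions, config$N)
  if (is_hfpp(precision) && config$summation == "REPRODUCIBLE")
    stop("reproducible summation is defined for the binary64 backend only; ",
         "high-precision runs use plain ordered accumulation", call. = FALSE)
  res <- cpp_run_network(
    unclass(params), config$Iapp, config$is_exc, settings$dt,
    as.double(settings$n_steps), settings$record_stride,
    sum_kind_code(config$summation), isTRUE(unified_accumulation),
    if (singularity == "limit") 1L else 0L,
    if (is_hfpp(precision)) precision$digits else 0L, ic)
  meta <- list(params = unclass(params), N = config$N, split = config$split,
               Ne = config$Ne, Ni = config$Ni, Iapp = config$Iapp,
               summation = config$summation, dt = settings$dt,
               duration = settings$duration,
               record_stride = settings$record_stride,
               precision = precision$mode, digits = precision$digits,
               initial_conditions = ic, singularity = singularity,
               unified_accumulation = isTRUE(unified_accumulation),
               package_version = as.character(utils::packageVersion("hhrepro")))
  structure(c(res, list(meta = meta)), class = "hh_trace")
}

#' @export
print.hh_trace <- function(x, ...) {
  m <- x$meta
  prec <- if (m$precision == "HFPP") sprintf("HFPP(%d)", m$digits) else "DFPP"
  cat(sprintf("<hh_trace> N=%d %s %s %s, dt=%s ms, %d samples over %g ms\n",
              m$N, m$split, prec, m$summation, m$dt, length(x$times),
              m$duration))
  cat(sprintf("  <A> in [%.4g, %.4g], <S> in [%.4g, %.4g]\n",
              min(x$A), max(x$A), min(x$S), max(x$S)))
  invisible(x)
}
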