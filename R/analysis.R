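check_same_grid <- function(t1, t2) {
  g1 <- t1$times
  g2 <- t2$times
  if (length(g1) != length(g2) || !isTRUE(all.equal(g1, g2, tolerance = 0)))
    stop(sprintf(
      "traces are on different time grids (%d samples [%g..%g] vs %d samples [%g..%g])",
      length(g1), g1[1], g1[length(g1)], length(g2), g2[1], g2[length(g2)]),
      call. = FALSE)
}

#' Pairwise absolute-error series
#'
#' The discrepancy between two runs over time, `eps(t) = |A_i(t) - A_j(t)|`,
#' computed pointwise in binary64 on the recorded network activity. For two
#' high-precision traces the binary64 averages agree to well below 1e-16, so
#' `exact = TRUE` computes the difference from the full decimal strings
#' instead (returning its magnitude as a double), which resolves
#' discrepancies down to the decimal working precision.
#'
#' @param trace_i,trace_j `hh_trace` objects on identical time grids.
#' @param exact Use the full-precision decimal samples (HFPP traces only).
#' @return A data frame with columns `time_ms` and `epsilon`.
#' @export
absolute_error_series <- function(trace_i, trace_j, exact = FALSE) {
  check_same_grid(trace_i, trace_j)
  if (exact) {
    if (is.null(trace_i$A_str) || is.null(trace_j$A_str))
      stop("exact comparison requires high-precision traces", call. = FALSE)
    eps <- cpp_dec_abs_diff(trace_i$A_str, trace_j$A_str)
  } else {
    eps <- abs(trace_i$A - trace_j$A)
  }
  data.frame(time_ms = trace_i$times, epsilon = eps)
}

#' First divergence time
#'
#' Earliest sample time at which the absolute error is strictly greater than
#' the threshold (matching the "> threshold" convention of divergence
#' reports), or `NA` if the error never exceeds it.
#'
#' @param err A data frame from [absolute_error_series()].
#' @param threshold Positive divergence threshold (default 1e-6).
#' @return Time in ms, or `NA_real_`.
#' @export
first_divergence_time <- function(err, threshold = 1e-6) {
  stopifnot(is.data.frame(err), all(c("time_ms", "epsilon") %in% names(err)))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  idx <- which(err$epsilon > threshold)
  if (length(idx) == 0L) return(NA_real_)
  err$time_ms[idx[1]]
}

#' All-to-all divergence matrix
#'
#' Pairwise first-crossing times over a set of traces on one grid: a
#' symmetric matrix whose `[i, j]` entry is the earliest time the absolute
#' error between traces `i` and `j` exceeds the threshold. Pairs that never
#' diverge are `NA` in the matrix and rendered as the full duration in the
#' printed report (the "dark red cell" convention: identical to the end).
#'
#' @param traces A list of `hh_trace` objects (>= 2) sharing a grid.
#' @param threshold Divergence threshold (default 1e-6).
#' @param exact Compare full-precision decimal samples (HFPP traces).
#' @return An object of class `hh_divergence`: the matrix (`times_ms`), the
#'   threshold, and the trace duration.
#' @export
divergence_matrix <- function(traces, threshold = 1e-6, exact = FALSE) {
  stopifnot(is.list(traces), length(traces) >= 2L)
  n <- length(traces)
  for (k in 2:n) check_same_grid(traces[[1]], traces[[k]])
  nm <- names(traces)
  if (is.null(nm)) nm <- paste0("trace", seq_len(n))
  m <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      err <- absolute_error_series(traces[[i]], traces[[j]], exact = exact)
      m[i, j] <- m[j, i] <- first_divergence_time(err, threshold)
    }
  }
  dur <- max(traces[[1]]$times)
  structure(list(times_ms = m, threshold = threshold, duration = dur),
            class = "hh_divergence")
}

#' @export
print.hh_divergence <- function(x, ...) {
  cat(sprintf("<hh_divergence> first time eps > %g (ms); %g = never diverged\n",
              x$threshold, x$duration))
  m <- x$times_ms
  m[is.na(m)] <- x$duration
  diag(m) <- x$duration
  print(round(m, 2))
  invisible(x)
}

#' Detect activity episodes by hysteresis
#'
#' Maximal intervals in which the network activity rises above an onset
#' threshold and stays up until falling below a lower offset threshold --
#' the elevated-activity episodes that alternate with quiescent periods in
#' the developing-network rhythm. The two thresholds (defaults on 0.3,
#' off 0.1) give hysteresis so within-episode ripple is not split into
#' spurious episodes.
#'
#' @param trace An `hh_trace`, or a numeric activity vector (then supply
#'   `times`).
#' @param on_threshold,off_threshold Hysteresis bounds,
#'   `on_threshold > off_threshold > 0`.
#' @param times Sample times (ms) when `trace` is a bare numeric vector.
#' @return A data frame with columns `start_ms`, `end_ms`, one row per
#'   episode (zero rows if none).
#' @export
detect_episodes <- function(trace, on_threshold = 0.3, off_threshold = 0.1,
                            times = NULL) {
  if (inherits(trace, "hh_trace")) {
    A <- trace$A
    times <- trace$times
  } else {
    A <- as.numeric(trace)
    if (is.null(times)) times <- seq_along(A)
  }
  if (!(on_threshold > off_threshold && off_threshold > 0))
    stop("need on_threshold > off_threshold > 0", call. = FALSE)
  up <- A > on_threshold
  down <- A < off_threshold
  starts <- numeric(0)
  ends <- numeric(0)
  inside <- FALSE
  start_t <- NA_real_
  for (i in seq_along(A)) {
    if (!inside && up[i]) {
      inside <- TRUE
      start_t <- times[i]
    } else if (inside && down[i]) {
      inside <- FALSE
      starts <- c(starts, start_t)
      ends <- c(ends, times[i])
    }
  }
  if (inside) {
    starts <- c(starts, start_t)
    ends <- c(ends, times[length(times)])
  }
  data.frame(start_ms = starts, end_ms = ends)
}

#' Standardized output filename for a scenario
#'
#' Encodes the information needed to replicate a run into the filename:
#' time step, pool sizes, leak reversal, simulated duration, precision, and
#' the applied-current ordering --
#' `hh_dt{dt}_Ne{Ne}_Ni{Ni}_vl{vl}_t{t}_{DFPP|HFPP<digits>}_{sort}.csv`,
#' with the decimal fields verbatim from the scenario's literals.
#'
#' @param spec An [scenario_spec()].
#' @return The filename as a string.
#' @examples
#' output_filename(scenario_spec("ALL_EXC", "RND", N = 100))
#' @export
output_filename <- function(spec) {
  stopifnot(inherits(spec, "hh_scenario"))
  Ne <- if (spec$split == "ALL_EXC") spec$N else as.integer(round(spec$N * 0.8))
  Ni <- spec$N - Ne
  prec <- if (is_hfpp(spec$precision))
    sprintf("HFPP%d", spec$precision$digits) else "DFPP"
  sprintf("hh_dt%s_Ne%d_Ni%d_vl%s_t%s_%s_%s.csv",
          spec$settings$dt, Ne, Ni, spec$params$V_l,
          format(spec$settings$duration, scientific = FALSE), prec, spec$sort)
}

#' Parse a standardized output filename
#'
#' Inverse of [output_filename()]: recovers the six encoded fields.
#'
#' @param name A filename produced by [output_filename()].
#' @return A list with `dt`, `Ne`, `Ni`, `vl`, `t`, `precision`, `digits`,
#'   `sort`.
#' @export
parse_output_filename <- function(name) {
  rx <- "^hh_dt([-0-9.eE+]+)_Ne([0-9]+)_Ni([0-9]+)_vl([-0-9.eE+]+)_t([-0-9.eE+]+)_(DFPP|HFPP[0-9]+)_(RND|ASD|DESC)\\.csv$"
  m <- regmatches(basename(name), regexec(rx, basename(name)))[[1]]
  if (length(m) != 8L)
    stop("not a standardized trace filename: ", name, call. = FALSE)
  prec <- m[7]
  list(dt = m[2], Ne = as.integer(m[3]), Ni = as.integer(m[4]), vl = m[5],
       t = m[6],
       precision = if (prec == "DFPP") "DFPP" else "HFPP",
       digits = if (prec == "DFPP") NA_integer_
                else as.integer(sub("HFPP", "", prec)),
       sort = m[8])
}
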