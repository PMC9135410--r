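scalars_to_backend <- function(x) {
  # accept a numeric vector (binary64) or a list of hh_scalar sharing a backend
  if (is.numeric(x)) return(list(mode = "DFPP", values = as.numeric(x)))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "hh_scalar"))) {
    if (length(x) == 0L) return(list(mode = "DFPP", values = numeric(0)))
    modes <- vapply(x, function(s) s$spec$mode, character(1))
    if (length(unique(modes)) != 1L)
      stop("all values must share one precision backend", call. = FALSE)
    if (modes[1] == "HFPP") {
      digs <- vapply(x, function(s) s$spec$digits, integer(1))
      if (length(unique(digs)) != 1L)
        stop("all values must share one precision backend", call. = FALSE)
      return(list(mode = "HFPP", digits = digs[1],
                  reprs = vapply(x, function(s) s$repr, character(1))))
    }
    return(list(mode = "DFPP",
                values = vapply(x, function(s) s$value, numeric(1))))
  }
  stop("x must be a numeric vector or a list of scalars", call. = FALSE)
}

#' Ordered (order-sensitive) summation
#'
#' Accumulates a vector strictly left to right, either naively
#' (`((v1 + v2) + v3) + ...`) or with classic Kahan compensation (a single
#' running correction term, initialized to zero). Both are order-sensitive:
#' permuting or re-associating the inputs can change the result, which is
#' precisely the mechanism by which the ordering of applied currents changes
#' simulation outcomes. The empty sum is exactly zero.
#'
#' @param x Numeric vector (binary64), or a list of `hh_scalar` sharing one
#'   backend.
#' @param strategy `"NAIVE"` or `"KAHAN"`.
#' @return A double for binary64 input; an `hh_scalar` for HFPP input.
#' @examples
#' sum_ordered(c(0.1, 0.1, 0.1, -0.3), "NAIVE")   # 5.551115123125783e-17
#' sum_ordered(c(-0.3, 0.1, 0.1, 0.1), "NAIVE")   # 2.7755575615628914e-17
#' sum_ordered(c(0.1, 0.1, 0.1, -0.3), "KAHAN")   # exactly 0
#' @export
sum_ordered <- function(x, strategy = c("NAIVE", "KAHAN")) {
  strategy <- match.arg(strategy)
  b <- scalars_to_backend(x)
  if (b$mode == "HFPP") {
    if (length(b$reprs) == 0L)
      return(make_scalar("0", precision_spec("HFPP", b$digits)))
    r <- cpp_sum_ordered_dec(b$reprs, strategy, b$digits)
    return(new_scalar(precision_spec("HFPP", b$digits), repr = r))
  }
  cpp_sum_ordered_f64(b$values, strategy)
}

#' Correctly rounded order-invariant summation
#'
#' Returns the binary64 value nearest (ties to even) the exact real sum of
#' the inputs, computed through a Kulisch-style long accumulator that
#' represents the running sum exactly. Because the exact sum does not depend
#' on the order of its terms, the result is bitwise identical under any
#' permutation of the input -- the property that makes presynaptic
#' conductance sums immune to commutation and association of their terms.
#'
#' Defined for the binary64 backend only: a high-precision decimal run is
#' treated as its own mitigation and uses plain ordered accumulation.
#'
#' @param x Numeric vector, or a list of DFPP `hh_scalar`s.
#' @return A double: the correctly rounded sum.
#' @examples
#' sum_reproducible(c(0.1, 0.1, 0.1, -0.3))  # 2.7755575615628914e-17
#' sum_reproducible(c(-0.3, 0.1, 0.1, 0.1))  # identical, any order
#' @export
sum_reproducible <- function(x) {
  b <- scalars_to_backend(x)
  if (b$mode == "HFPP")
    stop("reproducible summation is defined for the binary64 backend only; ",
         "high-precision runs use plain ordered accumulation", call. = FALSE)
  cpp_sum_reproducible(b$values)
}

#' Exact-expansion decimal oracle for binary64 sums
#'
#' Independent reference for [sum_reproducible()]: every binary64 value has a
#' finite exact decimal expansion, so the exact real sum can be accumulated
#' in a wide fixed-point *decimal* accumulator and rounded to binary64 once
#' at the end (through the C library's correctly rounded `strtod`). The two
#' routes share no arithmetic: one works in binary with a 2^-1074-aligned
#' accumulator, the other in decimal digits.
#'
#' @param x Numeric vector.
#' @return A double: the correctly rounded exact sum.
#' @export
sum_exact_decimal <- function(x) {
  stopifnot(is.numeric(x))
  cpp_sum_exact_oracle(as.numeric(x))
}
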