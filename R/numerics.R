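#' Precision specification for scalar arithmetic
#'
#' Describes the numeric backend used by scalars and simulations: `"DFPP"`
#' (default floating-point precision, IEEE binary64 with round-to-nearest,
#' ties-to-even) or `"HFPP"` (high floating-point precision, the package's
#' decimal floating-point arithmetic in which every operation rounds
#' half-to-even to a fixed number of significant decimal digits).
#'
#' @param mode `"DFPP"` or `"HFPP"`.
#' @param digits Significant decimal digits of the working precision; used
#'   only when `mode = "HFPP"`. Must lie in `[16, 120]` so that the decimal
#'   backend always dominates binary64 precision. Default 100.
#' @return An object of class `hh_precision`.
#' @examples
#' precision_spec("DFPP")
#' precision_spec("HFPP", digits = 50)
#' @export
precision_spec <- function(mode = c("DFPP", "HFPP"), digits = 100L) {
  mode <- match.arg(mode)
  digits <- as.integer(digits)
  if (mode == "HFPP") {
    if (length(digits) != 1L || is.na(digits) || digits < 16L || digits > 120L)
      stop("HFPP digits must be a single integer in [16, 120]", call. = FALSE)
  }
  structure(list(mode = mode, digits = if (mode == "HFPP") digits else NA_integer_),
            class = "hh_precision")
}

#' @export
print.hh_precision <- function(x, ...) {
  if (x$mode == "DFPP") cat("<precision: DFPP (IEEE binary64)>\n")
  else cat(sprintf("<precision: HFPP (%d significant decimal digits)>\n", x$digits))
  invisible(x)
}

is_hfpp <- function(spec) spec$mode == "HFPP"

new_scalar <- function(spec, value = NULL, repr = NULL) {
  structure(list(spec = spec, value = value, repr = repr), class = "hh_scalar")
}

#' Construct a scalar from a decimal literal string
#'
#' Materializes a decimal literal under a precision backend without routing
#' it through any other representation: under DFPP the result is the binary64
#' value nearest the literal (ties to even); under HFPP it is the decimal
#' value itself, exact whenever the literal has at most `digits` significant
#' digits. This literal-string initialization discipline is what makes the
#' same constants bit-identical across backends and implementations.
#'
#' @param literal A decimal literal string: optional sign, digits, optional
#'   fraction, optional e-exponent (ASCII).
#' @param spec A [precision_spec()].
#' @return An `hh_scalar`.
#' @examples
#' make_scalar("0.1", precision_spec("HFPP", 50))   # exactly one tenth
#' make_scalar("0.1", precision_spec("DFPP"))       # nearest binary64
#' @export
make_scalar <- function(literal, spec = precision_spec("DFPP")) {
  stopifnot(inherits(spec, "hh_precision"))
  if (!is.character(literal) || length(literal) != 1L)
    stop("literal must be a single character string", call. = FALSE)
  if (is_hfpp(spec)) {
    new_scalar(spec, repr = cpp_parse_literal(literal, spec$digits))
  } else {
    new_scalar(spec, value = cpp_strtod_strict(literal))
  }
}

#' @export
print.hh_scalar <- function(x, ...) {
  if (is_hfpp(x$spec))
    cat(sprintf("<HFPP(%d) scalar> %s\n", x$spec$digits, x$repr))
  else
    cat(sprintf("<DFPP scalar> %s\n", format(x$value, digits = 17)))
  invisible(x)
}

#' @export
as.double.hh_scalar <- function(x, ...) {
  if (is_hfpp(x$spec)) cpp_dec_to_double(x$repr) else x$value
}

coerce_operand <- function(e, template) {
  if (inherits(e, "hh_scalar")) return(e)
  if (is_hfpp(template$spec))
    stop("cannot mix a high-precision scalar with a bare number; ",
         "construct both operands with make_scalar()", call. = FALSE)
  if (!is.numeric(e) || length(e) != 1L)
    stop("scalar arithmetic requires single numeric operands", call. = FALSE)
  new_scalar(template$spec, value = as.numeric(e))
}

#' @export
Ops.hh_scalar <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") {
      if (is_hfpp(e1$spec))
        return(new_scalar(e1$spec, repr = cpp_dec_arith("-", "0", e1$repr, e1$spec$digits)))
      return(new_scalar(e1$spec, value = -e1$value))
    }
    if (.Generic == "+") return(e1)
    stop(sprintf("unary '%s' is not defined for scalars", .Generic), call. = FALSE)
  }
  template <- if (inherits(e1, "hh_scalar")) e1 else e2
  e1 <- coerce_operand(e1, template)
  e2 <- coerce_operand(e2, template)
  if (e1$spec$mode != e2$spec$mode ||
      (is_hfpp(e1$spec) && e1$spec$digits != e2$spec$digits))
    stop("operands use different precision backends; convert explicitly",
         call. = FALSE)
  if (.Generic %in% c("+", "-", "*", "/")) {
    if (is_hfpp(e1$spec))
      return(new_scalar(e1$spec,
                        repr = cpp_dec_arith(.Generic, e1$repr, e2$repr,
                                             e1$spec$digits)))
    v <- switch(.Generic,
                "+" = e1$value + e2$value,
                "-" = e1$value - e2$value,
                "*" = e1$value * e2$value,
                "/" = e1$value / e2$value)
    return(new_scalar(e1$spec, value = v))
  }
  if (.Generic %in% c("==", "!=", "<", "<=", ">", ">=")) {
    cmp <- if (is_hfpp(e1$spec)) cpp_dec_cmp(e1$repr, e2$repr)
           else sign(e1$value - e2$value)
    return(switch(.Generic,
                  "==" = cmp == 0, "!=" = cmp != 0,
                  "<" = cmp < 0, "<=" = cmp <= 0,
                  ">" = cmp > 0, ">=" = cmp >= 0))
  }
  stop(sprintf("'%s' is not defined for scalars", .Generic), call. = FALSE)
}

#' Exact decimal expansion of a scalar
#'
#' Renders the exact decimal expansion of the stored value, rounded
#' (half-to-even) or truncated to a number of significant digits. For a
#' binary64 scalar this is the exact decimal value of the bit pattern -- for
#' example the double nearest 0.1 expands to "0.10000000000000000555" at 20
#' significant digits -- not a shortest round-trip form.
#'
#' @param x An `hh_scalar`, or a single double (treated as binary64).
#' @param sig_digits Number of significant decimal digits to keep.
#' @param rounding `"round"` (half-to-even) or `"truncate"`.
#' @return A decimal string with exactly `sig_digits` significant digits.
#' @examples
#' to_decimal_string(make_scalar("0.1"), 20)
#' to_decimal_string(make_scalar("0.5"), 3)
#' @export
to_decimal_string <- function(x, sig_digits, rounding = c("round", "truncate")) {
  rounding <- match.arg(rounding)
  sig_digits <- as.integer(sig_digits)
  if (sig_digits < 1L) stop("sig_digits must be >= 1", call. = FALSE)
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.finite(x)) stop("x must be finite", call. = FALSE)
    return(cpp_double_exact_string(x, sig_digits, rounding))
  }
  stopifnot(inherits(x, "hh_scalar"))
  if (is_hfpp(x$spec)) {
    cpp_dec_format(x$repr, sig_digits, rounding)
  } else {
    if (!is.finite(x$value)) stop("x must be finite", call. = FALSE)
    cpp_double_exact_string(x$value, sig_digits, rounding)
  }
}

#' Nearest binary32 value of a decimal literal
#'
#' Rounds a decimal literal to the nearest IEEE binary32 (single precision)
#' value, ties to even, and returns it widened losslessly to binary64. Used
#' to inspect what a compiler that materializes literals in single precision
#' would store: `nearest_binary32("0.1")` expands exactly to
#' 0.100000001490116119384765625.
#'
#' @param literal A decimal literal string.
#' @return An `hh_scalar` under the DFPP backend holding the widened value.
#' @export
nearest_binary32 <- function(literal) {
  if (!is.character(literal) || length(literal) != 1L)
    stop("literal must be a single character string", call. = FALSE)
  new_scalar(precision_spec("DFPP"), value = cpp_nearest_binary32(literal))
}

#' Exponential of a scalar
#'
#' `exp(x)` under the scalar's backend. The DFPP path delegates to the
#' platform `exp`; bit-for-bit agreement of binary64 exponentials across
#' platforms is explicitly not promised (platform math libraries differ in
#' their last bit). The HFPP path is computed in-package by argument
#' reduction and a fixed-point polynomial with guard digits, accurate to the
#' backend's working precision, so it is identical wherever the package runs.
#'
#' @param x An `hh_scalar`.
#' @return An `hh_scalar` on the same backend.
#' @export
hp_exp <- function(x) {
  stopifnot(inherits(x, "hh_scalar"))
  if (is_hfpp(x$spec))
    new_scalar(x$spec, repr = cpp_dec_exp(x$repr, x$spec$digits))
  else
    new_scalar(x$spec, value = exp(x$value))
}

#' Small integer power by an explicit multiplication chain
#'
#' Computes `x^k` for `k` in 1..4 by repeated multiplication in the fixed
#' order `(((x*x)*x)*x)`, the only powers appearing in the ionic currents.
#' Both backends execute the same operation sequence, so the power function
#' can never be a source of cross-implementation divergence.
#'
#' @param x An `hh_scalar` or a single double.
#' @param k Integer exponent in 1..4.
#' @return Same type as `x`.
#' @export
hp_pow <- function(x, k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 4L)
    stop("k must be a single integer in 1..4", call. = FALSE)
  if (is.numeric(x)) {
    p <- x
    if (k >= 2L) p <- x * x
    if (k >= 3L) p <- p * x
    if (k == 4L) p <- p * x
    return(p)
  }
  stopifnot(inherits(x, "hh_scalar"))
  if (is_hfpp(x$spec))
    return(new_scalar(x$spec, repr = cpp_dec_pow_chain(x$repr, k, x$spec$digits)))
  new_scalar(x$spec, value = hp_pow(x$value, k))
}
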