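#' Generate the applied-current vector
#'
#' Draws `N` currents uniformly from -10 to 5 uA/cm^2 using splitmix64, a
#' 64-bit counter-based generator chosen because it is tiny, well-known, and
#' exactly reproducible from the written algorithm in any language (the
#' draw does not touch R's own RNG). Each value is emitted as a decimal
#' string with 17 significant digits, so every backend and implementation
#' materializes the identical binary64-representable quantity.
#'
#' @param seed Integer seed.
#' @param N Number of neurons.
#' @return Character vector of `N` decimal literals.
#' @examples
#' generate_iapp(1, 5)
#' @export
generate_iapp <- function(seed, N) {
  cpp_generate_iapp(as.double(seed), as.integer(N))
}

#' Order the applied-current vector
#'
#' `"RND"` keeps generation order, `"ASD"` sorts ascending, `"DESC"` sorts
#' descending; ties (impossible in practice for real draws) are broken
#' stably by original index. The multiset of values is unchanged -- only the
#' commutation of the eventual conductance sums differs.
#'
#' @param values Character vector of decimal literals (or numeric).
#' @param sort `"RND"`, `"ASD"`, or `"DESC"`.
#' @return The reordered vector, same type as the input.
#' @export
order_iapp <- function(values, sort = c("RND", "ASD", "DESC")) {
  sort <- match.arg(sort)
  if (length(values) == 0L) stop("values must be nonempty", call. = FALSE)
  if (sort == "RND") return(values)
  v <- if (is.character(values)) vapply(values, cpp_strtod_strict, numeric(1),
                                        USE.NAMES = FALSE) else as.numeric(values)
  idx <- if (sort == "ASD") order(v, seq_along(v)) else order(-v, seq_along(v))
  values[idx]
}

#' Scenario specification: one cell of the split-by-ordering matrix
#'
#' A scenario fixes everything needed to reproduce a run: the
#' excitatory/inhibitory split (association of the conductance sum), the
#' applied-current ordering (commutation of its terms), the seed from which
#' the currents are drawn, the precision backend, the summation strategy,
#' the integration settings, and the initial conditions. The `(split, sort)`
#' pair ranges over a 2 x 3 matrix; for a fixed seed all six cells share the
#' identical multiset of applied currents.
#'
#' @param split `"ALL_EXC"` or `"SPLIT_80_20"`.
#' @param sort `"RND"`, `"ASD"`, or `"DESC"`.
#' @param seed Integer seed for the applied-current draw (ignored when
#'   `iapp` is supplied).
#' @param N Neuron count (default 100).
#' @param precision [precision_spec()].
#' @param summation `"NAIVE"`, `"KAHAN"`, or `"REPRODUCIBLE"`.
#' @param settings [simulation_settings()].
#' @param initial_conditions List of literals for V, n, a, s.
#' @param params [model_parameters()].
#' @param iapp Optional explicit applied-current literals (pre-ordering),
#'   e.g. from [read_iapp()]; length N.
#' @param unified_accumulation Logical; see [run_simulation()].
#' @return An object of class `hh_scenario`.
#' @export
scenario_spec <- function(split = c("ALL_EXC", "SPLIT_80_20"),
                          sort = c("RND", "ASD", "DESC"),
                          seed = 1L, N = 100L,
                          precision = precision_spec("DFPP"),
                          summation = c("NAIVE", "KAHAN", "REPRODUCIBLE"),
                          settings = simulation_settings(),
                          initial_conditions = default_initial_conditions(),
                          params = model_parameters(),
                          iapp = NULL,
                          unified_accumulation = FALSE) {
  split <- match.arg(split)
  sort <- match.arg(sort)
  summation <- match.arg(summation)
  problems <- character(0)
  N <- as.integer(N)
  if (is.na(N) || N < 1L) problems <- c(problems, "N must be a positive integer")
  if (!inherits(precision, "hh_precision"))
    problems <- c(problems, "precision must be a precision_spec()")
  if (!inherits(settings, "hh_settings"))
    problems <- c(problems, "settings must be simulation_settings()")
  if (!inherits(params, "hh_parameters"))
    problems <- c(problems, "params must be model_parameters()")
  if (!is.null(iapp) && length(iapp) != N)
    problems <- c(problems, "iapp must have length N")
  if (inherits(precision, "hh_precision") && is_hfpp(precision) &&
      summation == "REPRODUCIBLE")
    problems <- c(problems,
                  "reproducible summation is defined for the binary64 backend only")
  if (length(problems))
    stop("invalid scenario:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  initial_conditions <- check_initial_conditions(initial_conditions, N)
  structure(list(split = split, sort = sort, seed = as.integer(seed), N = N,
                 precision = precision, summation = summation,
                 settings = settings, initial_conditions = initial_conditions,
                 params = params, iapp = iapp,
                 unified_accumulation = isTRUE(unified_accumulation)),
            class = "hh_scenario")
}

#' @export
print.hh_scenario <- function(x, ...) {
  prec <- if (is_hfpp(x$precision)) sprintf("HFPP(%d)", x$precision$digits) else "DFPP"
  cat(sprintf("<hh_scenario> %s x %s, N=%d, seed=%d, %s, %s, dt=%s, %g ms\n",
              x$split, x$sort, x$N, x$seed, prec, x$summation,
              x$settings$dt, x$settings$duration))
  invisible(x)
}

#' Materialize a scenario into simulation inputs
#'
#' Draws (or takes) the applied-current vector, applies the ordering, and
#' assigns pool membership positionally: the first 80 percent of
#' post-ordering indices are excitatory under `SPLIT_80_20`. Returns the
#' `(params, config, settings)` triple consumed by [run_simulation()].
#'
#' @param spec An [scenario_spec()].
#' @return A list with `params`, `config`, `settings`.
#' @export
build_scenario <- function(spec) {
  stopifnot(inherits(spec, "hh_scenario"))
  iapp <- if (is.null(spec$iapp)) generate_iapp(spec$seed, spec$N) else spec$iapp
  iapp <- order_iapp(iapp, spec$sort)
  config <- network_configuration(spec$N, spec$split, iapp, spec$summation)
  list(params = spec$params, config = config, settings = spec$settings)
}

#' Run one scenario
#'
#' Convenience wrapper: [build_scenario()] then [run_simulation()].
#'
#' @param spec An [scenario_spec()].
#' @return An `hh_trace`.
#' @export
run_scenario <- function(spec) {
  b <- build_scenario(spec)
  tr <- run_simulation(b$params, b$config, b$settings, spec$precision,
                       spec$initial_conditions,
                       unified_accumulation = spec$unified_accumulation)
  tr$meta$split <- spec$split
  tr$meta$sort <- spec$sort
  tr$meta$seed <- spec$seed
  tr
}

#' All six cells of the split-by-ordering matrix
#'
#' Expands a base scenario into the full 2 x 3 matrix (`ALL_EXC`,
#' `SPLIT_80_20`) x (`RND`, `ASD`, `DESC`), changing nothing else: for a
#' fixed seed the six cells share parameters, initial conditions, and the
#' applied-current multiset.
#'
#' @param base An [scenario_spec()] providing everything but split/sort.
#' @return A named list of six `hh_scenario` objects.
#' @export
scenario_matrix <- function(base) {
  stopifnot(inherits(base, "hh_scenario"))
  out <- list()
  for (split in c("ALL_EXC", "SPLIT_80_20")) {
    for (sort in c("RND", "ASD", "DESC")) {
      s <- base
      s$split <- split
      s$sort <- sort
      out[[paste(split, sort, sep = "_")]] <- s
    }
  }
  out
}

#' Write / read a scenario file
#'
#' Scenarios serialize to a flat YAML mapping carrying every field,
#' including the parameter and initial-condition literals, so a run is fully
#' reproducible from the file alone.
#'
#' @param spec An [scenario_spec()].
#' @param path File path.
#' @return `read_scenario()` returns an `hh_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "hh_scenario"))
  obj <- list(
    split = spec$split, sort = spec$sort, seed = spec$seed, N = spec$N,
    precision = spec$precision$mode,
    digits = if (is_hfpp(spec$precision)) spec$precision$digits else NULL,
    summation = spec$summation,
    dt = spec$settings$dt, duration = spec$settings$duration,
    record_stride = spec$settings$record_stride,
    initial_conditions = spec$initial_conditions,
    params = unclass(spec$params),
    iapp = spec$iapp,
    unified_accumulation = spec$unified_accumulation)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("split", "sort", "seed", "N", "precision", "summation", "dt",
            "duration", "record_stride", "initial_conditions", "params")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("scenario file is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  prec <- if (obj$precision == "HFPP")
    precision_spec("HFPP", obj$digits %||% 100L) else precision_spec("DFPP")
  ic <- lapply(obj$initial_conditions, as.character)
  scenario_spec(split = obj$split, sort = obj$sort, seed = obj$seed, N = obj$N,
                precision = prec, summation = obj$summation,
                settings = simulation_settings(obj$dt, obj$duration,
                                               obj$record_stride),
                initial_conditions = ic,
                params = do.call(model_parameters,
                                 lapply(obj$params, as.character)),
                iapp = if (!is.null(obj$iapp)) as.character(obj$iapp) else NULL,
                unified_accumulation = isTRUE(obj$unified_accumulation))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an applied-current file
#'
#' One decimal literal per line, ASCII. Such a file can pin the exact
#' currents of a published run for consumption by any implementation.
#'
#' @param iapp Character vector of decimal literals.
#' @param path File path.
#' @export
write_iapp <- function(iapp, path) {
  stopifnot(is.character(iapp))
  writeLines(iapp, path)
  invisible(path)
}

#' @rdname write_iapp
#' @export
read_iapp <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  vapply(x, cpp_strtod_strict, numeric(1))  # validates each literal
  trimws(x)
}
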