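#' Write / read a trace as CSV
#'
#' Traces serialize to plain CSV with columns `time_ms`, `A`, `S`, preceded
#' by `#`-prefixed metadata lines carrying the full provenance. Binary64
#' values are written with 17 significant digits so `read_trace(write_trace(x))`
#' reproduces the doubles bit for bit; high-precision traces write the
#' full-precision decimal strings in the `A` and `S` columns (and also parse
#' back to doubles on reading). Files from other implementations with the
#' same layout and grid are directly comparable with the divergence tools.
#'
#' @param trace An `hh_trace`.
#' @param path File path.
#' @return `read_trace()` returns an `hh_trace` (with `meta` recovered from
#'   the header comments); `write_trace()` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hh_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- trace$meta
  flat <- list(
    N = m$N, split = m$split, summation = m$summation, dt = m$dt,
    duration = m$duration, record_stride = m$record_stride,
    precision = m$precision,
    digits = if (is.null(m$digits) || is.na(m$digits)) "" else m$digits,
    singularity = m$singularity,
    unified_accumulation = m$unified_accumulation,
    sort = m$sort %||% "", seed = m$seed %||% "",
    package_version = m$package_version)
  for (nm in names(flat))
    writeLines(sprintf("# %s: %s", nm, flat[[nm]]), con)
  for (nm in names(m$params))
    writeLines(sprintf("# param_%s: %s", nm, m$params[[nm]]), con)
  for (nm in names(m$initial_conditions))
    writeLines(sprintf("# init_%s: %s", nm,
                       paste(m$initial_conditions[[nm]], collapse = ",")), con)
  writeLines(sprintf("# iapp: %s", paste(m$Iapp, collapse = ",")), con)
  writeLines("time_ms,A,S", con)
  hf <- !is.null(trace$A_str)
  a <- if (hf) trace$A_str else sprintf("%.17g", trace$A)
  s <- if (hf) trace$S_str else sprintf("%.17g", trace$S)
  writeLines(sprintf("%.17g,%s,%s", trace$times, a, s), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    stop("empty trace file: ", path, call. = FALSE)
  hdr <- grepl("^#", lines)
  meta_raw <- lines[hdr]
  body <- lines[!hdr]
  if (length(body) < 2L)
    stop(sprintf("malformed trace file %s: no data rows (line %d)", path,
                 length(lines)), call. = FALSE)
  if (body[1] != "time_ms,A,S")
    stop(sprintf("malformed trace file %s: expected header 'time_ms,A,S' at line %d",
                 path, which(!hdr)[1]), call. = FALSE)
  kv <- regmatches(meta_raw, regexec("^# ([^:]+): ?(.*)$", meta_raw))
  meta <- list()
  for (m in kv) if (length(m) == 3L) meta[[m[2]]] <- m[3]
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(lengths(rows) != 3L)
  if (length(bad))
    stop(sprintf("malformed trace file %s: expected 3 fields at line %d", path,
                 which(!hdr)[1] + bad[1]), call. = FALSE)
  rows <- do.call(rbind, rows)
  times <- as.numeric(rows[, 1])
  A <- as.numeric(rows[, 2])
  S <- as.numeric(rows[, 3])
  if (anyNA(times) || anyNA(A) || anyNA(S))
    stop("malformed trace file ", path, ": non-numeric sample", call. = FALSE)
  out <- list(times = times, A = A, S = S)
  if (identical(meta$precision, "HFPP")) {
    out$A_str <- rows[, 2]
    out$S_str <- rows[, 3]
  }
  params <- meta[grepl("^param_", names(meta))]
  names(params) <- sub("^param_", "", names(params))
  inits <- meta[grepl("^init_", names(meta))]
  names(inits) <- sub("^init_", "", names(inits))
  out$meta <- list(
    N = as.integer(meta$N %||% NA), split = meta$split,
    summation = meta$summation, dt = meta$dt,
    duration = as.numeric(meta$duration %||% NA),
    record_stride = as.integer(meta$record_stride %||% NA),
    precision = meta$precision,
    digits = if (nzchar(meta$digits %||% "")) as.integer(meta$digits) else NA_integer_,
    singularity = meta$singularity,
    unified_accumulation = identical(meta$unified_accumulation, "TRUE"),
    sort = meta$sort, seed = meta$seed,
    params = params,
    initial_conditions = lapply(inits, function(x) strsplit(x, ",")[[1]]),
    Iapp = if (!is.null(meta$iapp)) strsplit(meta$iapp, ",")[[1]] else NULL,
    package_version = meta$package_version)
  structure(out, class = "hh_trace")
}
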