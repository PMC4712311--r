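#' Read and write current traces, spike trains and release traces
#'
#' Current traces are two-column CSV files (`time_ms`, `current_pA`) at a
#' fixed sampling interval; sampling uniformity is validated on read
#' (maximum jitter below `1e-6 * dt`), and missing columns,
#' non-monotonic time or `NA` samples are rejected with the offending
#' line number. Spike trains are newline-separated floats (ms) or a JSON
#' list. Writing then reading reproduces the arrays exactly (values are
#' serialized at full precision).
#'
#' @param path File path.
#' @param kind Trace kind recorded on read (see [current_trace()]).
#' @return `read_trace()` returns a `"current_trace"`; `read_spikes()` a
#'   numeric vector; the writers return `path` invisibly.
#' @export
read_trace <- function(path, kind = "raw") {
  d <- read.csv(path, check.names = FALSE)
  for (col in c("time_ms", "current_pA"))
    if (!col %in% names(d))
      stop("'", path, "': missing column '", col, "'", call. = FALSE)
  if (nrow(d) < 2) stop("'", path, "': fewer than 2 samples", call. = FALSE)
  bad <- which(!is.finite(d$time_ms) | !is.finite(d$current_pA))
  if (length(bad))
    stop("'", path, "': non-finite value at line ", bad[1] + 1L,
         call. = FALSE)
  dtv <- diff(d$time_ms)
  if (any(dtv <= 0))
    stop("'", path, "': time not strictly increasing at line ",
         which(dtv <= 0)[1] + 2L, call. = FALSE)
  dt <- stats::median(dtv)
  jit <- which(abs(dtv - dt) > 1e-6 * dt)
  if (length(jit))
    stop("'", path, "': non-uniform sampling at line ", jit[1] + 2L,
         " (gap ", format(dtv[jit[1]]), " ms vs dt ", format(dt), " ms)",
         call. = FALSE)
  current_trace(d$current_pA, dt = dt, t0 = d$time_ms[1], kind = kind)
}

#' @param trace A `"current_trace"`.
#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  write.csv(format(as.data.frame(trace), digits = 17, trim = TRUE,
                   scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trace
#' @export
read_spikes <- function(path) {
  s <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.numeric(jsonlite::read_json(path, simplifyVector = TRUE))
  else scan(path, what = numeric(), quiet = TRUE,
            comment.char = "#")
  validate_spikes(s)
  s
}

#' @param spikes Numeric spike times (ms).
#' @rdname read_trace
#' @export
write_spikes <- function(spikes, path) {
  validate_spikes(spikes)
  writeLines(format(spikes, digits = 17, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' @param trace_df A `"sar_trace"` from [sar_simulate()].
#' @rdname read_trace
#' @export
write_release_trace <- function(trace_df, path) {
  stopifnot(inherits(trace_df, "sar_trace"))
  d <- as.data.frame(trace_df)[, c("time_ms", "q_sr", "q_ar", "n_sr",
                                   "n_ar", "r", "u_sr", "u_ar", "N")]
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param summary A `"period_summary"`.
#' @rdname read_trace
#' @export
write_period_summary <- function(summary, path) {
  write.csv(as.data.frame(summary)[, c("kind", "k", "mu", "sigma", "n")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trace
#' @export
read_period_summary <- function(path) {
  d <- read.csv(path)
  for (col in c("kind", "k", "mu", "sigma", "n"))
    if (!col %in% names(d))
      stop("'", path, "': missing column '", col, "'", call. = FALSE)
  structure(d, class = c("period_summary", "data.frame"))
}

#' @param kernel A [receptor_kernel()].
#' @rdname read_trace
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "receptor_kernel"))
  jsonlite::write_json(list(tau_syn_ms = kernel$tau_syn, A = kernel$A,
                            D_ms = kernel$D),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_trace
#' @export
read_kernel <- function(path) {
  k <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("tau_syn_ms", "A", "D_ms"))
    if (is.null(k[[nm]]))
      stop("kernel file '", path, "' is missing key '", nm, "'",
           call. = FALSE)
  receptor_kernel(tau_syn = k$tau_syn_ms, A = k$A, D = k$D_ms)
}
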