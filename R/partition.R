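#' Define synchronous and asynchronous release periods
#'
#' Splits the time axis into alternating spike-locked windows. Under the
#' `"data"` convention (matching deconvolved recordings) the synchronous
#' period of spike `k` starts `sync_offset` (default 0.3 ms) after the
#' spike and lasts `sync_duration` (default 1.1 ms); the asynchronous
#' period fills the gap until the next synchronous period (the last one
#' runs to `T`). Under the `"model"` convention (used when scoring
#' simulated release, where synchronous release occurs exactly at the
#' spike) the offset is 0. Overlapping synchronous windows are truncated
#' at the next window's start.
#'
#' @param spikes Spike times (ms), strictly increasing.
#' @param T End of the scored range (ms).
#' @param sync_offset Start of the synchronous window after each spike
#'   (ms).
#' @param sync_duration Length of the synchronous window (ms).
#' @param convention `"data"` (offset as given) or `"model"`
#'   (offset forced to 0).
#' @return Data frame of class `"sar_periods"`: columns `kind`
#'   (`"sr"`/`"ar"`), spike index `k`, `start`, `end` (half-open
#'   `[start, end)` in ms). The periods tile
#'   `[first synchronous start, T)` without overlap.
#' @examples
#' release_periods(regular_spikes(3, 100), T = 40)
#' @export
release_periods <- function(spikes, T, sync_offset = 0.3,
                            sync_duration = 1.1,
                            convention = c("data", "model")) {
  convention <- match.arg(convention)
  validate_spikes(spikes, T)
  stopifnot(length(spikes) >= 1, sync_duration > 0, sync_offset >= 0)
  if (convention == "model") sync_offset <- 0
  K <- length(spikes)
  s_start <- spikes + sync_offset
  s_end <- pmin(s_start + sync_duration,
                c(s_start[-1], Inf))  # truncate at next window's start
  a_start <- s_end
  a_end <- c(s_start[-1], T)
  out <- rbind(
    data.frame(kind = "sr", k = seq_len(K), start = s_start, end = s_end),
    data.frame(kind = "ar", k = seq_len(K), start = a_start, end = a_end))
  out <- out[out$end > out$start, ]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  structure(out, T = T, convention = convention,
            class = c("sar_periods", "data.frame"))
}

# map bin start times to period row index (NA outside); half-open intervals
period_index <- function(time_ms, periods) {
  idx <- rep(NA_integer_, length(time_ms))
  for (i in seq_len(nrow(periods))) {
    sel <- time_ms >= periods$start[i] - 1e-9 & time_ms < periods$end[i] - 1e-9
    idx[sel] <- i
  }
  idx
}

#' Integrate release over periods
#'
#' Sums the released amount falling into each period; bins are assigned
#' by bin-start membership in the half-open interval `[start, end)`. For
#' a `"sar_trace"` the per-bin amounts `q_sr + q_ar` are summed directly;
#' for a `"release_rate"` (deconvolved trace) the rate is multiplied by
#' the bin width, giving `M = sum q~ dt` in pA*ms.
#'
#' @param q A `"sar_trace"`, a `"release_rate"`, or a plain numeric
#'   vector (then `dt`, `t0` and `is_rate` apply).
#' @param periods A [release_periods()] data frame.
#' @param dt,t0 Grid of a plain numeric `q`.
#' @param is_rate Is a plain numeric `q` a rate (multiply by `dt`) or a
#'   per-bin amount?
#' @return Data frame: `kind`, `k`, `M` (one row per period).
#' @export
integrate_release <- function(q, periods, dt = NULL, t0 = 0,
                              is_rate = TRUE) {
  stopifnot(inherits(periods, "sar_periods"))
  if (inherits(q, "sar_trace")) {
    v <- q$q_sr + q$q_ar
    time_ms <- q$time_ms
    scale <- 1
  } else if (inherits(q, "release_rate")) {
    v <- q$q_scaled_pA
    time_ms <- q$time_ms
    scale <- attr(q, "dt")
  } else {
    if (is.null(dt)) stop("dt must be supplied for a numeric q", call. = FALSE)
    v <- as.numeric(q)
    time_ms <- t0 + (seq_along(v) - 1) * dt
    scale <- if (is_rate) dt else 1
  }
  idx <- period_index(time_ms, periods)
  M <- numeric(nrow(periods))
  ok <- !is.na(idx)
  if (any(ok)) {
    sums <- tapply(v[ok], idx[ok], sum)
    M[as.integer(names(sums))] <- sums * scale
  }
  data.frame(kind = periods$kind, k = periods$k, M = M)
}

#' Per-period trial statistics
#'
#' Combines per-trial integrated release amounts into per-period means
#' and standard deviations. The *population* formulas are used (divide by
#' `n`, not `n - 1`), exactly as in the fitting likelihood; with trial
#' counts as small as 3 the two differ appreciably, so this choice is
#' deliberate and load-bearing. Trials may cover different spike counts:
#' a period's `n` counts the trials that contain it. Degenerate
#' `sigma = 0` values (and any below the floor) are raised to
#' `sigma_floor_frac` times the grand mean of `M` so that the Gaussian
#' likelihood stays finite.
#'
#' @param trials List of per-trial data frames from
#'   [integrate_release()] (columns `kind`, `k`, `M`).
#' @param sigma_floor_frac Floor for `sigma`, as a fraction of the grand
#'   mean `M` (default 0.01).
#' @return Data frame of class `"period_summary"`: `kind`, `k`, `mu`,
#'   `sigma`, `n`, with attribute `M` (the per-trial value matrix,
#'   periods x trials, `NA` where a trial lacks the period).
#' @export
summarize_trials <- function(trials, sigma_floor_frac = 0.01) {
  stopifnot(is.list(trials), length(trials) >= 1)
  key <- function(d) paste(d$kind, d$k)
  keys <- unique(unlist(lapply(trials, key)))
  Mm <- matrix(NA_real_, nrow = length(keys), ncol = length(trials),
               dimnames = list(keys, NULL))
  for (i in seq_along(trials)) {
    d <- trials[[i]]
    Mm[key(d), i] <- d$M
  }
  n <- rowSums(!is.na(Mm))
  mu <- rowMeans(Mm, na.rm = TRUE)
  sigma <- sqrt(rowMeans((Mm - mu)^2, na.rm = TRUE))  # population, /n
  floor_ <- sigma_floor_frac * mean(mu)
  sigma_raw <- sigma
  sigma <- pmax(sigma, floor_)
  parts <- strsplit(keys, " ", fixed = TRUE)
  out <- data.frame(kind = vapply(parts, `[`, "", 1),
                    k = as.integer(vapply(parts, `[`, "", 2)),
                    mu = mu, sigma = sigma, n = n)
  out <- out[order(out$kind == "ar", out$k), ]
  rownames(out) <- NULL
  structure(out, M = Mm, sigma_floor = floor_, sigma_raw = sigma_raw,
            class = c("period_summary", "data.frame"))
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("period summary: %d periods (%d sync, %d async), %d trial(s)\n",
              nrow(x), sum(x$kind == "sr"), sum(x$kind == "ar"),
              ncol(attr(x, "M"))))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
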