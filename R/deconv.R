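#' Subtract the leak current from a raw recording
#'
#' The leak is estimated as the mean of the recorded current over a quiet
#' baseline window preceding the first spike. After subtraction the
#' synaptic current of an inhibitory synapse must be non-positive; samples
#' above `-eps` (noise excursions) are clamped to `-eps`, with
#' `eps = 0.2 pA` by default, so the output is strictly negative.
#'
#' @param raw A `"current_trace"` (raw IPSC recording, negative-going).
#' @param baseline Length-2 numeric `c(start, end)` in ms: the baseline
#'   window; must contain at least 20 samples.
#' @param eps Positive clamp level in pA.
#' @return A `"current_trace"` with `kind = "leak_corrected"` and an
#'   attribute `leak_pA` (the subtracted mean).
#' @export
subtract_leak <- function(raw, baseline, eps = 0.2) {
  stopifnot(inherits(raw, "current_trace"), length(baseline) == 2,
            baseline[2] > baseline[1], eps > 0)
  sel <- raw$time_ms >= baseline[1] & raw$time_ms < baseline[2]
  if (sum(sel) < 20)
    stop("baseline window contains fewer than 20 samples", call. = FALSE)
  leak <- mean(raw$current_pA[sel])
  I <- raw$current_pA - leak
  I[I > -eps] <- -eps
  out <- current_trace(I, attr(raw, "dt"), attr(raw, "t0"),
                       kind = "leak_corrected")
  attr(out, "leak_pA") <- leak
  attr(out, "eps") <- eps
  out
}

#' Estimate the receptor decay time constant from an isolated event
#'
#' Fits `|I(t)| = a * exp(-t / tau) + b` by nonlinear least squares to the
#' decay phase of an isolated postsynaptic event (a spontaneous quantum or
#' a single-spike response), starting at/after the event peak. Starting
#' values come from a log-linear regression on the offset-corrected decay.
#'
#' @param segment A `"current_trace"` beginning at the event peak, or a
#'   numeric vector of current samples with `dt` supplied.
#' @param dt Sampling interval (ms) when `segment` is a plain vector.
#' @return Object of class `"kernel_fit"`: `tau_syn` (ms), amplitude `a`,
#'   offset `b`, residual norm, standard error and an approximate 95%
#'   confidence interval for `tau_syn`, plus `flagged` if `tau_syn` falls
#'   outside (0.1, 100) ms.
#' @export
fit_kernel <- function(segment, dt = NULL) {
  if (inherits(segment, "current_trace")) {
    dt <- attr(segment, "dt")
    y <- segment$current_pA
  } else {
    if (is.null(dt)) stop("dt must be supplied", call. = FALSE)
    y <- as.numeric(segment)
  }
  # single polarity flip from the event peak (per-sample abs() would fold
  # noise and bias the tail, hence tau)
  if (y[which.max(abs(y))] < 0) y <- -y
  n <- length(y)
  if (n < 10) stop("segment too short to fit a decay", call. = FALSE)
  t <- (seq_len(n) - 1) * dt
  # the offset is estimated from the segment tail and held fixed: at low
  # SNR a free offset trades off against slow decays (a tau-b ridge)
  ntail <- max(20L, n %/% 10L)
  tail_idx <- (n - min(ntail, n - 1) + 1):n
  b0 <- mean(y[tail_idx])
  fit <- NULL
  b_used <- b0
  for (iter in 1:3) {
    b_used <- b0
    a0 <- max(y) - b0
    ypos <- pmax(y - b0, 1e-3 * a0)
    lf <- lm(log(ypos) ~ t, subset = ypos > 0.05 * a0)
    tau0 <- -1 / coef(lf)[2]
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- n * dt / 3
    fit <- tryCatch(
      nls(y ~ a * exp(-t / tau) + b0,
          start = list(a = a0, tau = tau0),
          control = list(maxiter = 200, warnOnly = TRUE),
          algorithm = "port",
          lower = c(a = 0, tau = 1e-3)),
      error = function(e) stop("kernel fit did not converge: ",
                               conditionMessage(e), call. = FALSE))
    cf <- coef(fit)
    # remove the decay's own tail contribution from the baseline estimate
    b_new <- mean(y[tail_idx] -
                    cf[["a"]] * exp(-t[tail_idx] / cf[["tau"]]))
    if (abs(b_new - b0) < 1e-9 * max(abs(b0), 1)) break
    b0 <- b_new
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  tau <- unname(cf["tau"])
  structure(list(tau_syn = tau, a = unname(cf["a"]), b = b_used,
                 resid_norm = sqrt(sum(residuals(fit)^2)),
                 se_tau = se,
                 ci_tau = tau + c(-1.96, 1.96) * se,
                 flagged = (tau <= 0.1 || tau >= 100),
                 fit = fit),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("receptor kernel fit: tau_syn = %.3f ms (95%% CI %.3f-%.3f), offset = %.3f pA\n",
              x$tau_syn, x$ci_tau[1], x$ci_tau[2], x$b))
  if (x$flagged) cat("  WARNING: tau_syn outside the plausible (0.1, 100) ms range\n")
  invisible(x)
}

#' Sequential constrained deconvolution of a current trace
#'
#' Recovers the scaled release rate `q~ = A * q` from a leak-corrected
#' current by a one-pass, bin-by-bin constrained inversion of the
#' exponential receptor model. At each bin the unconstrained release
#' estimate matches the measured current exactly; it is accepted only in
#' so far as the resulting predicted current, decaying with `tau_syn`,
#' stays below the measured trace (in magnitude) throughout a lookahead
#' window. Release can therefore never be asserted where the trace decays
#' faster than the receptor kernel, which is what makes the inversion of
#' sparse quantal events well-posed. The gain `A` is not identifiable, so
#' the output is always the scaled rate `A * q` (pA units).
#'
#' @param trace A `"current_trace"` with `kind = "leak_corrected"` (its
#'   magnitude is used), or any current trace whose magnitude is the
#'   synaptic current.
#' @param kernel A [receptor_kernel()]; `A` only fixes the internal scale
#'   and cancels in the output, `D` shifts the release times.
#' @param lookahead Lookahead window (ms); must be at least
#'   `3 * tau_syn`. Default `5 * tau_syn`.
#' @return Data frame of class `"release_rate"`: `time_ms`,
#'   `q_scaled_pA` (the rate `A q(t)` >= 0), with attributes `dt`, `t0`,
#'   `kernel`.
#' @examples
#' q <- numeric(2000); q[c(200, 900)] <- 3
#' I <- release_to_current(q, receptor_kernel(D = 0), dt = 0.05)
#' qr <- deconvolve(I, receptor_kernel(D = 0))
#' range(qr$q_scaled_pA)
#' @export
deconvolve <- function(trace, kernel, lookahead = 5 * kernel$tau_syn) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(kernel, "receptor_kernel"))
  dt <- attr(trace, "dt")
  if (lookahead < 3 * kernel$tau_syn)
    stop("lookahead must be at least 3 * tau_syn", call. = FALSE)
  delta <- as.integer(round(kernel$D / dt))
  I <- abs(trace$current_pA)
  qt <- cpp_deconvolve(I, kernel$A, kernel$tau_syn, dt,
                       as.integer(ceiling(lookahead / dt)), delta)
  # cpp returns A*p*... as rate already scaled by A: q~ = A*q
  structure(data.frame(time_ms = attr(trace, "t0") +
                         (seq_along(qt) - 1) * dt,
                       q_scaled_pA = qt),
            dt = dt, t0 = attr(trace, "t0"), kernel = kernel,
            class = c("release_rate", "data.frame"))
}

#' Estimate the transmission delay from release-rate peaks
#'
#' For each spike, finds the lag of the maximal release rate within a
#' short post-spike window; the transmission delay is the median lag.
#' Spikes with no detectable release peak (all-zero window) are excluded
#' with a warning.
#'
#' @param spikes Spike times (ms); at least 2.
#' @param q A `"release_rate"` data frame from [deconvolve()].
#' @param window Search window after each spike (ms); default 3.
#' @return List: `D` (median lag, ms), `lags` (per-spike), `used`
#'   (logical per spike).
#' @export
estimate_delay <- function(spikes, q, window = 3) {
  stopifnot(length(spikes) >= 2, inherits(q, "release_rate"))
  dt <- attr(q, "dt")
  lags <- rep(NA_real_, length(spikes))
  for (m in seq_along(spikes)) {
    sel <- which(q$time_ms >= spikes[m] & q$time_ms <= spikes[m] + window)
    if (!length(sel) || all(q$q_scaled_pA[sel] <= 0)) next
    lags[m] <- q$time_ms[sel[which.max(q$q_scaled_pA[sel])]] - spikes[m]
  }
  used <- !is.na(lags)
  if (!all(used))
    warning(sum(!used), " spike(s) had no detectable release peak and were excluded")
  if (!any(used)) stop("no release peak detected after any spike", call. = FALSE)
  list(D = median(lags[used]), lags = lags, used = used)
}
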