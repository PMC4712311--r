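#' Simulate the SAR synapse model
#'
#' Runs the two-sensor release model on a fixed time grid, driven by a
#' spike train. In `"stochastic"` mode the released and replenished
#' vesicle numbers are binomial draws per bin (the quantal model); in
#' `"deterministic"` mode the mean-field equations are integrated with
#' exact exponential updates and release is a continuous amount.
#'
#' Per-bin event order at spike bins: facilitation jumps (giving
#' `u(t+)`), synchronous release from the pre-spike pool, asynchronous
#' release from the remainder, replenishment, then exponential decay of
#' the release probabilities over the bin. Spike times are snapped to the
#' nearest grid point; a snapping distance beyond `dt/2` is an error.
#'
#' @param params A [sar_params()] object.
#' @param spikes Spike times in ms (strictly increasing, within `[0, T)`).
#' @param T Simulated duration (ms).
#' @param dt Bin width (ms); default 0.05 ms.
#' @param mode `"stochastic"` (binomial quantal draws) or
#'   `"deterministic"` (mean field).
#' @param seed Optional integer seed (stochastic mode).
#' @return A data frame of class `"sar_trace"` with one row per bin:
#'   `time_ms`, released amounts `q_sr`, `q_ar` (transmitter units per
#'   bin), counts `n_sr`, `n_ar`, `r` and pool size `N` (stochastic mode;
#'   `NA` otherwise), state `u_sr`, `u_ar`, and continuous resource `x`
#'   (deterministic mode). Attributes: `dt`, `t0`, `mode`, `params`,
#'   `spikes`.
#' @examples
#' p <- sar_params()
#' tr <- sar_simulate(p, regular_spikes(5, 100), T = 100, seed = 1)
#' colSums(tr[, c("q_sr", "q_ar")])
#' @export
sar_simulate <- function(params, spikes, T, dt = 0.05,
                         mode = c("stochastic", "deterministic"),
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "sar_params"), T > 0, dt > 0)
  validate_spikes(spikes, T)
  nbins <- as.integer(ceiling(T / dt))
  sb <- snap_spikes(spikes, dt)
  if (length(sb) && sb[length(sb)] >= nbins)
    stop("spike snapped outside the simulation grid", call. = FALSE)
  # binomial success probabilities must be valid for every reachable state
  if (params$U_max * dt > 1)
    stop("U_max * dt exceeds 1; decrease dt", call. = FALSE)
  if (dt / params$tau_d > 1)
    stop("dt / tau_d exceeds 1; decrease dt", call. = FALSE)

  time_ms <- (seq_len(nbins) - 1) * dt
  if (mode == "deterministic") {
    th <- c(params$tau_sr, params$U_sr, params$tau_ar, params$U_ar,
            params$tau_d, params$U_max, params$N_F * params$x0, params$U0)
    s <- cpp_sim_det(th, sb, nbins, dt)
    out <- data.frame(time_ms = time_ms, q_sr = s$q_sr, q_ar = s$q_ar,
                      n_sr = NA_integer_, n_ar = NA_integer_,
                      r = NA_integer_, u_sr = s$u_sr, u_ar = s$u_ar,
                      N = NA_integer_, x = s$x)
  } else {
    if (!is.null(seed)) set.seed(seed)
    th <- c(params$tau_sr, params$U_sr, params$tau_ar, params$U_ar,
            params$tau_d, params$U_max, params$N_F, params$x0, params$U0)
    s <- cpp_sim_stoch(th, sb, nbins, dt)
    out <- data.frame(time_ms = time_ms, q_sr = params$x0 * s$n_sr,
                      q_ar = params$x0 * s$n_ar, n_sr = s$n_sr,
                      n_ar = s$n_ar, r = s$r, u_sr = s$u_sr,
                      u_ar = s$u_ar, N = s$N, x = params$x0 * s$N)
  }
  structure(out, dt = dt, t0 = 0, mode = mode, params = params,
            spikes = spikes, class = c("sar_trace", "data.frame"))
}

#' Simulate repeated stochastic trials
#'
#' Convenience wrapper running [sar_simulate()] `trials` times in
#' stochastic mode with per-trial seeds `seed + trial - 1`.
#'
#' @inheritParams sar_simulate
#' @param trials Number of trials.
#' @param seed Base seed; trial `i` uses `seed + i - 1`.
#' @return List of `"sar_trace"` objects.
#' @export
sar_simulate_trials <- function(params, spikes, T, dt = 0.05, trials = 1,
                                seed = 1) {
  lapply(seq_len(trials), function(i)
    sar_simulate(params, spikes, T, dt, mode = "stochastic",
                 seed = seed + i - 1))
}

#' @export
print.sar_trace <- function(x, ...) {
  cat(sprintf("SAR release trace: %d bins, dt = %g ms, mode = %s\n",
              nrow(x), attr(x, "dt"), attr(x, "mode")))
  cat(sprintf("  spikes: %d; total release q_sr = %.4g, q_ar = %.4g\n",
              length(attr(x, "spikes")), sum(x$q_sr), sum(x$q_ar)))
  invisible(x)
}

# ---- elementary state updates (reference implementations) -------------------
# These operate on a plain state list(u_sr, u_ar, N or x) and mirror the
# compiled simulator bin-for-bin; they are the documented primitives and the
# oracle used by the test-suite.

#' Elementary SAR state updates
#'
#' Single-bin building blocks of the simulator, exposed for inspection and
#' testing: exponential decay of the release probabilities between spikes,
#' the per-spike facilitation jumps, and one stochastic
#' release-and-replenish draw.
#'
#' `sar_decay()` applies the exact interspike solution
#' `u_sr <- u_sr * exp(-dt/tau_sr)` and
#' `u_ar <- U0 + (u_ar - U0) * exp(-dt/tau_ar)`.
#' `sar_facilitate()` applies `u_sr <- u_sr + U_sr (1 - u_sr)` and
#' `u_ar <- u_ar + U_ar (U_max - u_ar)`.
#' `sar_release_step()` draws, in order, `n_sr ~ Binomial(N, u_sr)` (spike
#' bins only), `n_ar ~ Binomial(N - n_sr, u_ar * dt)` and a replenishment
#' count from `Binomial(N_F - N, dt/tau_d)`, then updates
#' `N <- N - n_sr - n_ar + r`.
#'
#' @param state Named list with `u_sr`, `u_ar` and (for the release step)
#'   pool size `N`.
#' @param dt Time step (ms).
#' @param params A [sar_params()] object.
#' @param is_spike Logical: is this a spike bin (facilitation already
#'   applied)?
#' @return Updated state list; `sar_release_step()` additionally carries
#'   `n_sr`, `n_ar`, `r`.
#' @examples
#' st <- list(u_sr = 0.3, u_ar = 0.1)
#' sar_decay(st, dt = 2, sar_params(tau_sr = 2))$u_sr  # 0.3 * exp(-1)
#' @export
sar_decay <- function(state, dt, params) {
  stopifnot(dt > 0)
  state$u_sr <- state$u_sr * exp(-dt / params$tau_sr)
  state$u_ar <- params$U0 + (state$u_ar - params$U0) * exp(-dt / params$tau_ar)
  state
}

#' @rdname sar_decay
#' @export
sar_facilitate <- function(state, params) {
  state$u_sr <- state$u_sr + params$U_sr * (1 - state$u_sr)
  state$u_ar <- state$u_ar + params$U_ar * (params$U_max - state$u_ar)
  state
}

#' @rdname sar_decay
#' @export
sar_release_step <- function(state, is_spike, dt, params) {
  p_ar <- state$u_ar * dt
  p_rep <- dt / params$tau_d
  if (p_ar > 1 || p_rep > 1)
    stop("dt too large: binomial probabilities exceed 1", call. = FALSE)
  N <- state$N
  stopifnot(N >= 0, N <= params$N_F)
  n_sr <- if (is_spike) rbinom(1, N, state$u_sr) else 0L
  n_ar <- rbinom(1, N - n_sr, p_ar)
  r <- rbinom(1, params$N_F - N, p_rep)
  state$N <- N - n_sr - n_ar + r
  state$n_sr <- n_sr
  state$n_ar <- n_ar
  state$r <- r
  state
}
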