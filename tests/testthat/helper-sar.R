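# Reference parameter set used across tests: the sar_params() defaults
# (tau_sr 2 ms, U_sr 0.3, tau_ar 12 ms, U_ar 0.005, U_max 0.5 /ms,
# tau_d 30 ms, N_F 271), with overrides.
fig_params <- function(...) sar_params(...)

# Pure-R mirror of the stochastic simulator, drawing rbinom in the same
# order as the compiled loop; used as a bit-exact oracle.
r_sim_stoch <- function(params, spikes, T, dt) {
  nbins <- as.integer(ceiling(T / dt))
  sb <- as.integer(round(spikes / dt))
  st <- list(u_sr = 0, u_ar = params$U0, N = params$N_F)
  out <- data.frame(n_sr = integer(nbins), n_ar = integer(nbins),
                    r = integer(nbins), N = integer(nbins),
                    u_sr = numeric(nbins), u_ar = numeric(nbins))
  for (i in seq_len(nbins) - 1L) {
    spike <- i %in% sb
    if (spike) st <- sar_facilitate(st, params)
    st <- sar_release_step(st, spike, dt, params)
    out[i + 1L, ] <- list(st$n_sr, st$n_ar, st$r, st$N, st$u_sr, st$u_ar)
    st <- sar_decay(st, dt, params)
  }
  out
}

# Classical two-variable short-term-plasticity recursion (facilitation u,
# resources x), evaluated spike-to-spike in closed form. Independent oracle
# for the deterministic simulator with the asynchronous pathway off.
stp_per_spike_release <- function(spikes, tau_f, U, tau_d, X_F) {
  u <- 0; x <- X_F; tprev <- NULL
  rel <- numeric(length(spikes))
  for (m in seq_along(spikes)) {
    if (!is.null(tprev)) {
      dtm <- spikes[m] - tprev
      u <- u * exp(-dtm / tau_f)
      x <- X_F + (x - X_F) * exp(-dtm / tau_d)
    }
    u <- u + U * (1 - u)
    rel[m] <- u * x
    x <- x - rel[m]
    tprev <- spikes[m]
  }
  rel
}

# Summaries of simulated stochastic release for fitting tests.
sim_summary <- function(params, spikes, T, trials, seed, dt = 0.05) {
  per <- release_periods(spikes, T, convention = "model")
  tr <- sar_simulate_trials(params, spikes, T, dt, trials = trials,
                            seed = seed)
  summarize_trials(lapply(tr, integrate_release, periods = per))
}
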