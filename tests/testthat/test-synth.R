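test_that("noiseless fixtures invert end-to-end through the pipeline", {
  p <- sar_params(U_ar = 0.02)
  spikes <- regular_spikes(5, 100, t0 = 50)
  kern <- receptor_kernel(tau_syn = 5, A = 10, D = 0.75)
  fx <- make_fixture(p, spikes, T = 200, trials = 1, kernel = kern,
                     noise_sd = 0, leak = -40, seed = 6)
  corr <- subtract_leak(fx$currents[[1]], baseline = c(0, 45))
  qr <- deconvolve(corr, kern)
  truth <- kern$A * (fx$releases[[1]]$q_sr + fx$releases[[1]]$q_ar) / 0.05
  # epsilon clamping perturbs only near-zero stretches; compare where the
  # signal lives
  err <- sqrt(sum((qr$q_scaled_pA - truth)^2) / sum(truth^2))
  expect_lt(err, 0.02)
})

test_that("a release-free noisy trace deconvolves to the floor residue only", {
  p <- sar_params(U_sr = 0, U_ar = 0, U0 = 0)
  kern <- receptor_kernel(tau_syn = 5, A = 10, D = 0)
  fx <- make_fixture(p, regular_spikes(3, 100, t0 = 50), T = 150,
                     trials = 1, kernel = kern, noise_sd = 0.1,
                     leak = -30, seed = 8)
  corr <- subtract_leak(fx$currents[[1]], baseline = c(0, 45))
  qr <- deconvolve(corr, kern)
  # bounded by the epsilon-floor residue (plus the small noise scale)
  expect_lt(sum(qr$q_scaled_pA) * 0.05,
            0.5 * (1 + 150 / kern$tau_syn))
})

test_that("fixtures show depressing spike-locked IPSCs and post-train release", {
  p <- sar_params(tau_sr = 1, U_sr = 0.11, tau_ar = 13, U_ar = 0.0035,
                  U_max = 0.5, tau_d = 60, N_F = 271, x0 = 1)
  spikes <- regular_spikes(10, 100, t0 = 20)
  kern <- receptor_kernel(tau_syn = 5, A = 10 / p$x0, D = 0.75)
  fx <- make_fixture(p, spikes, T = 250, trials = 20, kernel = kern,
                     noise_sd = 1, leak = -30, seed = 12)
  peak_per_spike <- function(I, t) {
    vapply(spikes, function(s)
      min(I$current_pA[t >= s & t < s + 5]), numeric(1))
  }
  peaks <- rowMeans(vapply(fx$currents, function(I)
    peak_per_spike(I, I$time_ms), numeric(length(spikes))))
  # spike-locked IPSC amplitudes depress over the train
  expect_lt(mean(-peaks[8:10]), mean(-peaks[1:2]))
  # asynchronous quanta persist after the last spike
  post <- vapply(fx$releases, function(tr)
    sum(tr$n_ar[tr$time_ms > max(spikes) + 5]), numeric(1))
  expect_gt(mean(post), 0)
})

test_that("trial-averaged quantal current variance scales with the quantum size", {
  # holding the synaptic strength w*X_F fixed while splitting the pool into
  # more, smaller vesicles: across-trial variance of the asynchronous
  # current is proportional to w*x0
  spikes <- regular_spikes(10, 100)
  kern0 <- receptor_kernel(tau_syn = 5, A = 1, D = 0)
  X_F <- 271
  NFs <- c(100, 271, 1000)
  vars <- vapply(NFs, function(nf) {
    p <- sar_params(U_ar = 0.02, N_F = nf, x0 = X_F / nf)
    at <- numeric(0)
    v <- vapply(1:150, function(i) {
      tr <- sar_simulate(p, spikes, T = 120, seed = 7000 + i)
      I <- release_to_current(tr, kern0, component = "ar")
      # asynchronous plateau late in the train
      mean(I$current_pA[I$time_ms >= 80 & I$time_ms <= 100])
    }, numeric(1))
    var(v)
  }, numeric(1))
  x0s <- X_F / NFs
  fit <- lm(vars ~ x0s + 0)
  r2 <- summary(fit)$r.squared
  expect_gt(r2, 0.9)
  # monotone in x0 once ordered
  o <- order(x0s)
  expect_true(all(diff(vars[o]) > 0))
})

test_that("the recovery report is deterministic and exact in the zero-noise limit", {
  # deterministic-mode data with on-grid truths: the fit must return the
  # truth for every identifiable parameter, giving R^2 = 1
  spikes <- regular_spikes(10, 100)
  T <- 100
  grid <- sar_grid(tau_sr = c(4, 7, 10), U_sr = c(0.1, 0.3, 0.5),
                   tau_ar = c(8, 14, 20), U_arU_max = c(0.002, 0.006, 0.01),
                   tau_d = c(20, 50, 80), U_max = c(0.2, 0.6, 1))
  truths <- list(
    list(tau_sr = 7, U_sr = 0.1, tau_ar = 8, U_ar = 0.002 / 0.2,
         tau_d = 50, U_max = 0.2),
    list(tau_sr = 4, U_sr = 0.3, tau_ar = 14, U_ar = 0.006 / 0.6,
         tau_d = 20, U_max = 0.6),
    list(tau_sr = 10, U_sr = 0.5, tau_ar = 20, U_ar = 0.01 / 1,
         tau_d = 80, U_max = 1))
  est <- t(vapply(truths, function(th) {
    pred <- sar_predict_periods(th, spikes, T)
    sm <- data.frame(kind = pred$kind, k = pred$k, mu = pred$M,
                     sigma = 0.01 * mean(pred$M), n = 1)
    class(sm) <- c("period_summary", "data.frame")
    f <- sar_fit(sm, spikes, T, grid = grid, n_sp = 10)
    coef(f)[c("tau_sr", "U_sr", "tau_ar", "tau_d", "U_arU_max")]
  }, numeric(5)))
  for (j in seq_len(ncol(est))) {
    tv <- vapply(truths, function(th)
      if (colnames(est)[j] == "U_arU_max") th$U_ar * th$U_max
      else th[[colnames(est)[j]]], numeric(1))
    expect_equal(unname(est[, j]), tv, tolerance = 1e-9)
  }
})

test_that("small recovery runs reproduce bit-for-bit under a fixed seed", {
  g1 <- sarsyn:::recovery_grid_stage1(n = 3)
  g2 <- sarsyn:::recovery_grid_stage2(n = 3, n_umax = 3)
  r1 <- sar_recovery(n_settings = 2, trials = 5, n_spikes = 6,
                     grid1 = g1, grid2 = g2, seed = 9, refine = 1)
  r2 <- sar_recovery(n_settings = 2, trials = 5, n_spikes = 6,
                     grid1 = g1, grid2 = g2, seed = 9, refine = 1)
  expect_identical(r1$settings, r2$settings)
  expect_identical(r1$r2, r2$r2)
  expect_s3_class(r1, "sar_recovery")
  expect_output(print(r1), "recovery study")
  expect_error(sar_recovery(n_settings = 2, trials = 5,
                            grid1 = sar_grid(tau_sr = c(5, 8)),
                            seed = 1),
               "does not cover")
})
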