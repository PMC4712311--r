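test_that("decay follows the exact interspike exponential solution", {
  p <- sar_params(tau_sr = 2, tau_ar = 12, U0 = 0.1, U_max = 0.5)
  st <- list(u_sr = 0.3, u_ar = 0.4)

  # closed form after one step of dt = tau_sr
  s1 <- sar_decay(st, 2, p)
  expect_equal(s1$u_sr, 0.3 * exp(-1))
  # cross-check against fine-step Euler integration of du/dt = -u/tau
  euler <- function(u0, tau, dt, n = 1e5) {
    h <- dt / n
    u <- u0
    for (i in seq_len(n)) u <- u - h * u / tau
    u
  }
  expect_equal(s1$u_sr, euler(0.3, 2, 2), tolerance = 1e-4)

  # long-time limits: u_sr -> 0, u_ar -> U0
  s2 <- sar_decay(st, 1e6, p)
  expect_equal(s2$u_sr, 0)
  expect_equal(s2$u_ar, 0.1)
})

test_that("facilitation jumps from rest and at saturation", {
  p <- sar_params(U_sr = 0.3, U_ar = 0.005, U_max = 0.5)
  rest <- list(u_sr = 0, u_ar = 0)
  j <- sar_facilitate(rest, p)
  expect_equal(j$u_sr, 0.3)            # U_sr exactly
  expect_equal(j$u_ar, 0.005 * 0.5)    # U_ar * U_max
  sat <- sar_facilitate(list(u_sr = 1, u_ar = 0.5), p)
  expect_equal(sat$u_sr, 1)
  expect_equal(sat$u_ar, 0.5)
})

test_that("two-spike asynchronous facilitation matches the closed form", {
  p <- sar_params(tau_ar = 12, U_ar = 0.005, U_max = 0.5, U0 = 0)
  for (isi in c(5, 10, 25)) {
    st <- list(u_sr = 0, u_ar = 0)
    st <- sar_facilitate(st, p)
    st <- sar_decay(st, isi, p)
    st <- sar_facilitate(st, p)
    expect_equal(st$u_ar,
                 p$U_ar * p$U_max *
                   (1 + (1 - p$U_ar) * exp(-isi / p$tau_ar)))
  }
  # and the gridded simulator agrees at spike bins
  tr <- sar_simulate(p, c(0, 10), T = 20, dt = 0.05,
                     mode = "deterministic")
  expect_equal(tr$u_ar[tr$time_ms == 10],
               p$U_ar * p$U_max * (1 + (1 - p$U_ar) * exp(-10 / p$tau_ar)),
               tolerance = 1e-12)
})

test_that("release-and-replenish draws respect the empty-pool edge cases", {
  p <- sar_params(N_F = 50, tau_d = 30)
  set.seed(1)
  st <- sar_release_step(list(u_sr = 0.5, u_ar = 0.4, N = 0), TRUE, 0.05, p)
  expect_identical(st$n_sr, 0L)
  expect_identical(st$n_ar, 0L)
  expect_true(st$r >= 0 && st$r <= 50)

  # u_ar = 0, no spike: asynchronous release is impossible
  st2 <- sar_release_step(list(u_sr = 0.5, u_ar = 0, N = 30), FALSE, 0.05, p)
  expect_identical(st2$n_sr, 0L)
  expect_identical(st2$n_ar, 0L)
})

test_that("synchronous draw moments match the binomial formulas", {
  # N = 271, p = 0.11: mean N p = 29.81, variance N p (1 - p) = 26.5309
  p <- sar_params(N_F = 271, U_sr = 0.11, tau_d = 1e9, U_ar = 0)
  set.seed(42)
  draws <- replicate(1e5, {
    sar_release_step(list(u_sr = 0.11, u_ar = 0, N = 271L), TRUE, 0.05,
                     p)$n_sr
  })
  expect_equal(mean(draws), 271 * 0.11, tolerance = 0.005)
  expect_equal(var(draws), 271 * 0.11 * 0.89, tolerance = 0.02)
})

test_that("compiled stochastic simulator is draw-for-draw the R recursion", {
  p <- sar_params(N_F = 40, x0 = 1, U0 = 0.02)
  spikes <- c(0, 10, 20, 25)
  set.seed(7)
  cpp <- sar_simulate(p, spikes, T = 40, dt = 0.5, mode = "stochastic")
  set.seed(7)
  ref <- r_sim_stoch(p, spikes, T = 40, dt = 0.5)
  expect_identical(cpp$n_sr, ref$n_sr)
  expect_identical(cpp$n_ar, ref$n_ar)
  expect_identical(cpp$r, ref$r)
  expect_equal(cpp$N, ref$N)
  expect_equal(cpp$u_sr, ref$u_sr)
  expect_equal(cpp$u_ar, ref$u_ar)
})

test_that("rest is absorbing: no spikes and U0 = 0 gives no release", {
  p <- sar_params(U0 = 0)
  tr <- sar_simulate(p, numeric(0), T = 50, seed = 1)
  expect_true(all(tr$q_sr == 0))
  expect_true(all(tr$q_ar == 0))
  expect_true(all(tr$N == p$N_F))
})

test_that("pool conservation and state bounds hold over random settings", {
  set.seed(123)
  for (rep in 1:10) {
    p <- sar_params(tau_sr = runif(1, 0.5, 10), U_sr = runif(1, 0, 1),
                    tau_ar = runif(1, 2, 40), U_ar = runif(1, 0, 0.2),
                    U_max = runif(1, 0.1, 2), tau_d = runif(1, 10, 100),
                    N_F = sample(5:300, 1), U0 = runif(1, 0, 0.05))
    ns <- sample(1:12, 1)
    spikes <- sort(sample(seq(0, 95, by = 0.05), ns))
    tr <- sar_simulate(p, spikes, T = 100, seed = rep)
    expect_true(all(tr$N >= 0 & tr$N <= p$N_F))
    # N(t) = N_F - cum(n_sr + n_ar) + cum(r) at every bin
    expect_equal(tr$N,
                 p$N_F - cumsum(tr$n_sr + tr$n_ar) + cumsum(tr$r))
    expect_true(all(tr$u_sr >= 0 & tr$u_sr <= 1))
    expect_true(all(tr$u_ar >= p$U0 - 1e-12 &
                      tr$u_ar <= p$U_max + 1e-12))
    # synchronous release only in spike bins
    expect_lte(sum(tr$q_sr > 0), ns)
  }
})

test_that("deterministic mode with the asynchronous pathway off is the STP model", {
  p <- sar_params(tau_sr = 3, U_sr = 0.25, U_ar = 0, U_max = 0.5,
                  tau_d = 45, N_F = 100, x0 = 2.5)
  spikes <- regular_spikes(8, 100)
  tr <- sar_simulate(p, spikes, T = 100, dt = 0.05,
                     mode = "deterministic")
  rel <- tr$q_sr[tr$q_sr > 0]
  oracle <- stp_per_spike_release(spikes, tau_f = 3, U = 0.25,
                                  tau_d = 45, X_F = 250)
  expect_equal(rel, oracle, tolerance = 1e-12)
})

test_that("spikes snap to the nearest bin and invalid input is rejected", {
  p <- sar_params()
  # snapping: a spike within dt/2 of a grid point lands in that bin
  tr <- sar_simulate(p, c(0, 10.017), T = 50, dt = 0.05, seed = 1)
  expect_true(all(which(tr$q_sr > 0) %in% c(1L, 201L)))
  expect_gt(tr$u_sr[201], tr$u_sr[200])  # facilitation lands in bin 201
  expect_error(sar_simulate(p, c(10, 5), T = 50), "increasing")
  expect_error(sar_simulate(p, c(0, 60), T = 50), "\\[0, T\\)")
  expect_error(sar_simulate(sar_params(U_max = 2), c(0), T = 10, dt = 1),
               "U_max")
})

test_that("spontaneous floor U0 produces ongoing release without spikes", {
  p <- sar_params(U0 = 0.02)
  tr <- sar_simulate(p, numeric(0), T = 200, seed = 5)
  expect_gt(sum(tr$n_ar), 0)
  expect_true(all(tr$u_ar == 0.02))
})
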