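test_that("the period log-likelihood matches hand values and dnorm", {
  # zero residual: only the normalizers remain
  mu <- c(1, 2, 3); sigma <- c(0.5, 1, 2)
  expect_equal(sar_loglik(mu, mu, sigma),
               -sum(log(sqrt(2 * pi) * sigma)))
  # single period, mu = 1, sigma = 1, prediction 2
  expect_equal(sar_loglik(2, 1, 1), -0.5 - log(sqrt(2 * pi)))
  # random case against a sum of normal log-densities
  set.seed(14)
  M <- runif(20); m <- runif(20); s <- runif(20, 0.1, 2)
  expect_equal(sar_loglik(M, m, s), sum(dnorm(M, m, s, log = TRUE)))
})

test_that("predictions are normalized to the data total and scale-free in X_F", {
  p <- sar_params(U_sr = 0.2, U_ar = 0.01, U_max = 0.5, tau_d = 40)
  spikes <- regular_spikes(10, 100)
  sm <- sim_summary(p, spikes, T = 100, trials = 10, seed = 21)
  pred <- sar_predict_periods(p, spikes, T = 100, n_sp = 10,
                              normalize_to = sm)
  expect_equal(sum(pred$M[pred$k <= 10]), sum(sm$mu[sm$k <= 10]))

  # the deterministic model is linear in X_F, so normalized predictions
  # are invariant to the pool scale used in the generating parameters
  base <- sar_predict_periods(p, spikes, T = 100, normalize_to = 100)
  for (xf in c(10, 100)) {
    th <- unclass(p); th$x0 <- xf / th$N_F
    px <- do.call(sar_params, th)
    tr <- sar_simulate(px, spikes, T = 100, mode = "deterministic")
    per <- release_periods(spikes, 100, convention = "model")
    M <- integrate_release(tr, per)
    M$M <- M$M * 100 / sum(M$M)
    expect_equal(M$M, base$M, tolerance = 1e-9)
  }
})

test_that("U_ar = 0 predicts zero asynchronous release", {
  p <- sar_params(U_ar = 0, U0 = 0)
  pred <- sar_predict_periods(p, regular_spikes(5, 100), T = 50)
  expect_true(all(pred$M[pred$kind == "ar"] == 0))
  expect_true(all(pred$M[pred$kind == "sr"] > 0))
})

test_that("grid search recovers an on-grid truth from noiseless data", {
  spikes <- regular_spikes(10, 100)
  T <- 100
  grid <- sar_grid(tau_sr = c(1, 2, 3), U_sr = c(0.1, 0.2, 0.3),
                   tau_ar = c(8, 12, 16), U_arU_max = c(0.002, 0.004, 0.008),
                   tau_d = c(30, 50, 70), U_max = c(0.25, 0.5, 1))
  truth <- list(tau_sr = 2, U_sr = 0.2, tau_ar = 16, U_ar = 0.004 / 0.5,
                tau_d = 50, U_max = 0.5)
  pred <- sar_predict_periods(truth, spikes, T)
  sm <- data.frame(kind = pred$kind, k = pred$k, mu = pred$M,
                   sigma = pmax(0.01 * mean(pred$M), 1e-8),
                   n = 1)
  class(sm) <- c("period_summary", "data.frame")
  f <- sar_fit(sm, spikes, T, grid = grid, n_sp = 10)
  cf <- coef(f)
  # recovered exactly, up to the U_max / U_ar redundancy
  for (nm in c("tau_sr", "U_sr", "tau_ar", "tau_d"))
    expect_equal(unname(cf[[nm]]), truth[[nm]], tolerance = 1e-9)
  expect_equal(unname(cf[["U_arU_max"]]), 0.004, tolerance = 1e-9)
  # the optimum dominates every other grid point (spot-checked rows)
  set.seed(3)
  bt <- sarsyn:::build_theta(grid, list())
  ev <- sarsyn:::eval_theta_matrix(bt$theta[sample(nrow(bt$theta), 50), ],
                                   f$ctx)
  expect_true(all(ev$logLik <= f$logLik + 1e-8))
})

test_that("fixing parameters restricts the search and is honored", {
  p <- sar_params(U_sr = 0.2, U_ar = 0.01, U_max = 0.5, tau_d = 40)
  spikes <- regular_spikes(10, 100)
  sm <- sim_summary(p, spikes, T = 100, trials = 15, seed = 33)
  f <- sar_fit(sm, spikes, T = 100, grid = sar_grid(n = 3),
               fixed = list(U_max = 1, tau_d = 40))
  expect_equal(unname(coef(f)[["U_max"]]), 1)
  expect_equal(unname(coef(f)[["tau_d"]]), 40)
  expect_false("U_max" %in% f$free)
  expect_error(sar_fit(sm, spikes, T = 100, grid = sar_grid(n = 3),
                       fixed = list(bogus = 1)), "unknown fixed")
})

test_that("likelihood is invariant to trial relabeling and common time shifts", {
  p <- sar_params(U_sr = 0.2, U_ar = 0.01, U_max = 0.5, tau_d = 40)
  spikes <- regular_spikes(8, 100)
  per <- release_periods(spikes, 80, convention = "model")
  tr <- sar_simulate_trials(p, spikes, 80, trials = 12, seed = 2)
  Ms <- lapply(tr, integrate_release, periods = per)
  sm_a <- summarize_trials(Ms)
  sm_b <- summarize_trials(rev(Ms))
  f_a <- sar_fit(sm_a, spikes, 80, grid = sar_grid(n = 3), n_sp = 8)
  f_b <- sar_fit(sm_b, spikes, 80, grid = sar_grid(n = 3), n_sp = 8)
  expect_equal(f_a$logLik, f_b$logLik)
  expect_equal(coef(f_a), coef(f_b))

  # shifting spikes and scoring window together changes nothing
  spikes2 <- spikes + 20
  per2 <- release_periods(spikes2, 100, convention = "model")
  tr2 <- sar_simulate_trials(p, spikes2, 100, trials = 12, seed = 2)
  # NOTE: different absolute spike bins, same relative protocol
  f_c <- sar_fit(summarize_trials(lapply(tr2, integrate_release,
                                         periods = per2)),
                 spikes2, 100, grid = sar_grid(n = 3), n_sp = 8)
  expect_equal(f_c$logLik, f_a$logLik, tolerance = 1e-6)
})

test_that("likelihood-ratio intervals match the quadratic closed form", {
  # logL = -(x - a)^2 / (2 s^2): half-width at ratio r is s * sqrt(-2 ln r)
  a <- 3; s <- 0.7
  x <- seq(0, 6, by = 0.001)
  ci <- sarsyn:::lr_interval(x, -(x - a)^2 / (2 * s^2), 0.9)
  hw <- s * sqrt(-2 * log(0.9))
  expect_equal(ci$interval, c(a - hw, a + hw), tolerance = 0.002)
  expect_false(any(ci$open))
  # flat likelihood spans the scan
  ci2 <- sarsyn:::lr_interval(x, rep(0, length(x)), 0.9)
  expect_equal(ci2$interval, range(x))
  expect_true(all(ci2$open))
})

test_that("confidence intervals contain the estimate and flag open ends", {
  p <- sar_params(U_sr = 0.2, U_ar = 0.01, U_max = 0.5, tau_d = 40)
  spikes <- regular_spikes(10, 100)
  sm <- sim_summary(p, spikes, T = 100, trials = 25, seed = 44)
  # refine the optimum first: intervals are scanned around the estimate
  f <- sar_fit(sm, spikes, T = 100, grid = sar_grid(n = 4), n_sp = 10,
               refine = 2)
  ci <- confint(f, ratio = 0.9, refine = 3)
  cf <- coef(f)
  for (nm in rownames(ci)) {
    expect_lte(ci[nm, "lower"], cf[[nm]] + 1e-9)
    expect_gte(ci[nm, "upper"], cf[[nm]] - 1e-9)
  }
  # U_max is near-redundant with U_ar at fixed product: expect a wide,
  # typically open-ended interval
  expect_gt(diff(ci["U_max", ]), 0)
})

test_that("fit methods expose the standard modelling interface", {
  p <- sar_params(U_sr = 0.2, U_ar = 0.01, U_max = 0.5, tau_d = 40)
  spikes <- regular_spikes(10, 100)
  sm <- sim_summary(p, spikes, T = 100, trials = 15, seed = 50)
  f <- sar_fit(sm, spikes, T = 100, grid = sar_grid(n = 3), n_sp = 10)
  expect_s3_class(f, "sar_fit")
  expect_named(coef(f), c("tau_sr", "U_sr", "tau_ar", "U_ar", "tau_d",
                          "U_max", "U_arU_max"))
  expect_s3_class(logLik(f), "logLik")
  expect_equal(nrow(fitted(f)), 20)
  expect_length(residuals(f), length(f$ctx$mu))
  expect_output(print(f), "grid-search fit")
  expect_output(print(summary(f)), "Pearson residuals")
  pr <- predict(f, params = coef(f))
  expect_equal(pr$M, fitted(f)$M, tolerance = 1e-9)
  sims <- simulate(f, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "sar_trace")
})
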