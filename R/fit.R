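#' Parameter grids for the SAR model fit
#'
#' The fit is an exhaustive grid search, so the search space is given as
#' one value grid per free parameter. Each element may be an explicit
#' vector of grid values, or a length-2 range that is expanded to `n`
#' equally spaced points. Because `U_max` and `U_ar` both scale the
#' facilitation of the asynchronous rate and are individually poorly
#' constrained by short spike trains, the asynchronous increment is
#' gridded through the product `U_arU_max = U_ar * U_max` by default
#' (`U_ar` is backed out per grid point); a direct `U_ar` grid may be
#' supplied instead.
#'
#' Defaults are the reference search spaces for a fast-spiking to
#' pyramidal-cell synapse: `tau_sr` in \[1, 4\] ms, `U_sr` in
#' \[0.02, 0.3\], `tau_ar` in \[4, 32\] ms, `U_ar * U_max` in
#' \[0.004, 0.024\], `tau_d` in \[20, 80\] ms, `U_max` in
#' \[0.125, 2\] 1/ms.
#'
#' @param tau_sr,U_sr,tau_ar,U_arU_max,tau_d,U_max Grids or length-2
#'   ranges.
#' @param U_ar Optional explicit grid for `U_ar` itself; when supplied it
#'   replaces the product grid.
#' @param n Number of points used to expand length-2 ranges.
#' @return Named list of grids, class `"sar_grid"`.
#' @export
sar_grid <- function(tau_sr = c(1, 4), U_sr = c(0.02, 0.3),
                     tau_ar = c(4, 32), U_arU_max = c(0.004, 0.024),
                     tau_d = c(20, 80), U_max = c(0.125, 2),
                     U_ar = NULL, n = 5) {
  expand1 <- function(v) {
    stopifnot(is.numeric(v), length(v) >= 1, !anyNA(v))
    if (length(v) == 2 && v[2] > v[1]) seq(v[1], v[2], length.out = n)
    else sort(unique(v))
  }
  g <- list(tau_sr = expand1(tau_sr), U_sr = expand1(U_sr),
            tau_ar = expand1(tau_ar), tau_d = expand1(tau_d),
            U_max = expand1(U_max))
  if (!is.null(U_ar)) g$U_ar <- expand1(U_ar)
  else g$U_arU_max <- expand1(U_arU_max)
  structure(g, class = "sar_grid")
}

# natural-parameter theta matrix (tau_sr, U_sr, tau_ar, U_ar, tau_d, U_max)
# from a grid list with fixed overrides; lexicographic expand.grid order
# (first dimension varies fastest) defines the tie-break.
build_theta <- function(grid, fixed = list()) {
  g <- unclass(grid)
  bad <- setdiff(names(fixed),
                 c("tau_sr", "U_sr", "tau_ar", "tau_d", "U_max",
                   "U_ar", "U_arU_max"))
  if (length(bad)) stop("unknown fixed parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if ("U_ar" %in% names(fixed)) g$U_arU_max <- NULL
  for (nm in names(fixed)) g[[nm]] <- fixed[[nm]]
  dims <- c("tau_sr", "U_sr", "tau_ar", "tau_d", "U_max",
            intersect(c("U_ar", "U_arU_max"), names(g)))
  ex <- do.call(expand.grid, c(g[dims], KEEP.OUT.ATTRS = FALSE))
  if (!"U_ar" %in% names(ex)) ex[["U_ar"]] <- ex$U_arU_max / ex$U_max
  if (any(ex$U_ar < 0 | ex$U_ar > 1))
    stop("grid implies U_ar outside [0, 1]", call. = FALSE)
  list(theta = as.matrix(ex[, c("tau_sr", "U_sr", "tau_ar", "U_ar",
                                "tau_d", "U_max")]),
       design = ex,
       free = names(Filter(function(v) length(v) > 1, g[dims])))
}

#' Gaussian period log-likelihood
#'
#' The fitting objective: independent Gaussians per release period,
#' `sum_r sum_k [ -(M(k) - mu(k))^2 / (2 sigma(k)^2) - log(sqrt(2 pi) sigma(k)) ]`.
#'
#' @param M_pred Predicted integrated release per period.
#' @param mu,sigma Observed per-period mean and (population) standard
#'   deviation, aligned with `M_pred`.
#' @return The log-likelihood (scalar).
#' @export
sar_loglik <- function(M_pred, mu, sigma) {
  stopifnot(length(M_pred) == length(mu), length(mu) == length(sigma),
            all(sigma > 0), all(is.finite(c(M_pred, mu, sigma))))
  sum(-(M_pred - mu)^2 / (2 * sigma^2) - log(sqrt(2 * pi) * sigma))
}

# shared protocol preparation for grid evaluation
fit_context <- function(summary, spikes, T, dt, n_sp, sync_duration,
                        convention, U0) {
  validate_spikes(spikes, T)
  periods <- release_periods(spikes, T, sync_duration = sync_duration,
                             convention = convention)
  nbins <- as.integer(ceiling(T / dt))
  sb <- snap_spikes(spikes, dt)
  bt <- (seq_len(nbins) - 1) * dt
  pid <- period_index(bt, periods)
  pid0 <- ifelse(is.na(pid), -1L, as.integer(pid - 1L))
  key <- paste(periods$kind, periods$k)
  skey <- paste(summary$kind, summary$k)
  use_s <- summary$k <= n_sp & skey %in% key
  prow <- match(skey[use_s], key)  # summary row -> period row
  if (anyNA(prow)) stop("summary contains periods absent from the protocol",
                        call. = FALSE)
  list(periods = periods, nbins = nbins, sb = sb, pid0 = pid0,
       use_s = use_s, prow = prow, mu = summary$mu[use_s],
       sigma = summary$sigma[use_s], dt = dt, U0 = U0)
}

# evaluate log-likelihood (and normalized predictions) over a theta matrix
eval_theta_matrix <- function(theta, ctx) {
  Mraw <- cpp_det_periods(theta, ctx$sb, ctx$pid0, nrow(ctx$periods),
                          ctx$nbins, ctx$dt, 1.0, ctx$U0)
  Mu <- Mraw[, ctx$prow, drop = FALSE]
  tot <- rowSums(Mu)
  scale <- ifelse(tot > 0, sum(ctx$mu) / tot, 0)
  Mn <- Mu * scale
  const <- sum(log(sqrt(2 * pi) * ctx$sigma))
  ll <- -0.5 * rowSums(sweep(sweep(Mn, 2, ctx$mu), 2, ctx$sigma, "/")^2) -
    const
  ll[tot <= 0] <- -Inf
  list(logLik = ll, Mraw = Mraw, scale = scale)
}

#' Fit the SAR model to period summaries by grid-search maximum likelihood
#'
#' Estimates the kinetic parameters
#' `theta = (tau_sr, U_sr, tau_ar, U_ar, tau_d, U_max)` from per-period
#' release statistics. For every point of the Cartesian parameter grid
#' the deterministic mean-field model is simulated with total pool
#' `X_F = 1` (the released amount is proportional to `X_F`, so the
#' absolute scale is not identifiable), release is integrated over the
#' same periods as the data, all predictions are rescaled by a common
#' factor so that their sum matches the summed observed means, and the
#' Gaussian log-likelihood [sar_loglik()] is evaluated on the first
#' `n_sp` spikes. The estimate is the exhaustive argmax; ties resolve to
#' the first point in grid order (first dimension varying fastest).
#'
#' Parameters can be held fixed via `fixed` (e.g. `list(U_max = 1)`, or
#' the two-stage scheme that first fits all six coarsely, then fixes
#' `U_sr` and `tau_d` and refines the rest — see [sar_recovery()]).
#'
#' @param summary A [summarize_trials()] data frame (observed `mu`,
#'   `sigma` per period).
#' @param spikes Spike times of the stimulation protocol (ms).
#' @param T End of the scored range (ms).
#' @param grid A [sar_grid()].
#' @param fixed Named list of parameters held constant (any of `tau_sr`,
#'   `U_sr`, `tau_ar`, `tau_d`, `U_max`, `U_ar`, `U_arU_max`).
#' @param n_sp Number of spikes whose periods enter the likelihood
#'   (default 10).
#' @param dt Simulation bin width (ms).
#' @param sync_duration Synchronous-period length (ms).
#' @param convention Period convention, see [release_periods()];
#'   `"model"` scores simulated release from the spike onward.
#' @param U0 Spontaneous asynchronous floor (1/ms) used in the forward
#'   model.
#' @param refine Number of local grid-refinement passes after the
#'   initial exhaustive search: each pass re-grids every free dimension
#'   with the same number of points over plus/minus one previous grid
#'   step around the current optimum (clipped to the search space),
#'   roughly halving the resolution per pass. The search stays an
#'   exhaustive grid evaluation within each pass. Default 0 (single
#'   pass over `grid`).
#' @return Object of class `"sar_fit"` with methods `print`, `summary`,
#'   `coef`, `logLik`, `fitted`, `residuals`, `predict`, `confint`,
#'   `plot`, `simulate`.
#' @examples
#' \donttest{
#' p <- sar_params(tau_sr = 2, U_sr = 0.2, tau_ar = 12, U_ar = 0.008,
#'                 U_max = 0.5, tau_d = 40)
#' spk <- regular_spikes(10, 100)
#' tr <- sar_simulate_trials(p, spk, T = 100, trials = 20, seed = 1)
#' per <- release_periods(spk, 100, convention = "model")
#' s <- summarize_trials(lapply(tr, integrate_release, periods = per))
#' f <- sar_fit(s, spk, T = 100, grid = sar_grid(n = 4))
#' coef(f)
#' }
#' @export
sar_fit <- function(summary, spikes, T, grid = sar_grid(),
                    fixed = list(), n_sp = 10, dt = 0.05,
                    sync_duration = 1.1,
                    convention = c("model", "data"), U0 = 0,
                    refine = 0) {
  convention <- match.arg(convention)
  stopifnot(inherits(summary, "period_summary") || is.data.frame(summary))
  ctx <- fit_context(summary, spikes, T, dt, n_sp, sync_duration,
                     convention, U0)
  cur_grid <- grid
  bt <- build_theta(cur_grid, fixed)
  ev <- eval_theta_matrix(bt$theta, ctx)
  best <- which.max(ev$logLik)
  for (pass in seq_len(refine)) {
    cur_grid <- local_grid(cur_grid, grid, bt$design[best, ], bt$free)
    bt <- build_theta(cur_grid, fixed)
    ev <- eval_theta_matrix(bt$theta, ctx)
    best <- which.max(ev$logLik)
  }
  theta_hat <- bt$theta[best, ]
  Mn_full <- ev$Mraw[best, ] * ev$scale[best]
  fitted_df <- data.frame(kind = ctx$periods$kind, k = ctx$periods$k,
                          M = Mn_full)
  structure(list(
    coefficients = c(theta_hat,
                     U_arU_max = unname(theta_hat["U_ar"] *
                                          theta_hat["U_max"])),
    logLik = ev$logLik[best],
    A_scale = ev$scale[best],
    fitted = fitted_df,
    data = summary,
    grid = bt$design,
    grid_spec = grid,
    fixed = fixed,
    free = bt$free,
    spikes = spikes, T = T, dt = dt, n_sp = n_sp,
    sync_duration = sync_duration, convention = convention, U0 = U0,
    ctx = ctx,
    call = match.call()),
    class = "sar_fit")
}

# evaluate one theta (natural parameterization) in a fit's context
eval_theta_one <- function(object, theta) {
  th <- matrix(theta[c("tau_sr", "U_sr", "tau_ar", "U_ar", "tau_d",
                       "U_max")], nrow = 1)
  ev <- eval_theta_matrix(th, object$ctx)
  list(logLik = ev$logLik[1],
       fitted = data.frame(kind = object$ctx$periods$kind,
                           k = object$ctx$periods$k,
                           M = ev$Mraw[1, ] * ev$scale[1]))
}

#' Predicted per-period release for a parameter set
#'
#' Runs the deterministic SAR model with `X_F = 1` under a spike
#' protocol, integrates release over the periods, and (optionally)
#' rescales the predictions so that their sum matches a reference total
#' — the same normalization used inside [sar_fit()], reflecting that
#' only the shape of the release profile, not its absolute scale, is
#' identifiable.
#'
#' @param params A [sar_params()] object or named vector with `tau_sr`,
#'   `U_sr`, `tau_ar`, `U_ar`, `tau_d`, `U_max`.
#' @inheritParams sar_fit
#' @param normalize_to `NULL` (raw `X_F = 1` amounts), a scalar total, or
#'   a `period_summary` (then the sum of `mu` over the first `n_sp`
#'   spikes is matched).
#' @return Data frame `kind`, `k`, `M`.
#' @export
sar_predict_periods <- function(params, spikes, T, n_sp = 10, dt = 0.05,
                                sync_duration = 1.1,
                                convention = c("model", "data"),
                                U0 = 0, normalize_to = NULL) {
  convention <- match.arg(convention)
  th <- unlist(params[c("tau_sr", "U_sr", "tau_ar", "U_ar", "tau_d",
                        "U_max")])
  periods <- release_periods(spikes, T, sync_duration = sync_duration,
                             convention = convention)
  nbins <- as.integer(ceiling(T / dt))
  bt <- (seq_len(nbins) - 1) * dt
  pid <- period_index(bt, periods)
  pid0 <- ifelse(is.na(pid), -1L, as.integer(pid - 1L))
  M <- cpp_det_periods(matrix(th, nrow = 1), snap_spikes(spikes, dt),
                       pid0, nrow(periods), nbins, dt, 1.0, U0)[1, ]
  out <- data.frame(kind = periods$kind, k = periods$k, M = M)
  if (!is.null(normalize_to)) {
    use <- out$k <= n_sp
    target <- if (is.data.frame(normalize_to))
      sum(normalize_to$mu[normalize_to$k <= n_sp])
    else as.numeric(normalize_to)
    tot <- sum(out$M[use])
    out$M <- if (tot > 0) out$M * target / tot else out$M
  }
  out
}

# ---- methods ---------------------------------------------------------------

#' @export
coef.sar_fit <- function(object, ...) object$coefficients

#' @export
logLik.sar_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$free),
            nobs = length(object$ctx$mu), class = "logLik")
}

#' @export
fitted.sar_fit <- function(object, ...) object$fitted

#' @export
residuals.sar_fit <- function(object, type = c("pearson", "response"),
                              ...) {
  type <- match.arg(type)
  d <- object$data
  f <- object$fitted
  m <- merge(as.data.frame(d), f, by = c("kind", "k"),
             suffixes = c("", ".fit"))
  r <- m$mu - m$M
  if (type == "pearson") r <- r / m$sigma
  setNames(r, paste(m$kind, m$k))
}

#' @export
print.sar_fit <- function(x, digits = 4, ...) {
  cat("SAR model grid-search fit\n")
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  log-likelihood: %.4f over %d periods (first %d spikes)\n",
              x$logLik, length(x$ctx$mu), x$n_sp))
  invisible(x)
}

#' @param object,x A `"sar_fit"`.
#' @param ... Unused.
#' @rdname sar_fit
#' @export
summary.sar_fit <- function(object, ...) {
  structure(list(fit = object,
                 resid = residuals(object),
                 n_periods = length(object$ctx$mu)),
            class = "summary.sar_fit")
}

#' @export
print.summary.sar_fit <- function(x, ...) {
  print(x$fit)
  cat("  Pearson residuals over fitted periods:\n")
  print(summary(unname(x$resid)))
  invisible(x)
}

#' @export
predict.sar_fit <- function(object, params = NULL, ...) {
  if (is.null(params)) return(object$fitted)
  th <- unlist(params[c("tau_sr", "U_sr", "tau_ar", "U_ar", "tau_d",
                        "U_max")])
  eval_theta_one(object, th)$fitted
}

#' Likelihood-ratio confidence intervals for a SAR fit
#'
#' For each free parameter a fine one-dimensional scan is run around the
#' estimate with all other parameters held at their fitted values; the
#' interval collects the scanned values whose likelihood is at least
#' `ratio` (default 0.9) of the maximum — on the likelihood scale, not
#' the log scale. Intervals reaching the edge of the search space are
#' flagged open-ended.
#'
#' @param object A `"sar_fit"`.
#' @param parm Parameters to scan (default: all free ones).
#' @param ratio Likelihood-ratio threshold in (0, 1).
#' @param refine Scan resolution multiplier relative to the fit grid.
#' @param ... Unused.
#' @return Matrix with columns `lower`, `upper` and attributes
#'   `open_lower`, `open_upper` (logical per parameter).
#' @export
confint.sar_fit <- function(object, parm = NULL, ratio = 0.9,
                            refine = 5, ...) {
  stopifnot(ratio > 0, ratio < 1)
  free <- object$free
  if (is.null(parm)) parm <- free
  parm <- intersect(parm, free)
  theta_hat <- object$coefficients
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  open_lo <- open_hi <- setNames(logical(length(parm)), parm)
  for (p in parm) {
    gv <- sort(unique(object$grid[[p]]))
    scan <- seq(min(gv), max(gv), length.out = max(refine * length(gv), 11))
    # keep the estimate itself on the scan
    scan <- sort(unique(c(scan, theta_hat[[p]])))
    ll <- vapply(scan, function(v) {
      th <- theta_hat
      th[[p]] <- v
      if (p == "U_arU_max") th[["U_ar"]] <- v / th[["U_max"]]
      if (p == "U_max" && "U_arU_max" %in% free)
        th[["U_ar"]] <- theta_hat[["U_arU_max"]] / v
      eval_theta_one(object, th)$logLik
    }, numeric(1))
    ci <- lr_interval(scan, ll, ratio)
    out[p, ] <- ci$interval
    open_lo[p] <- ci$open[1] && ci$interval[1] <= min(gv)
    open_hi[p] <- ci$open[2] && ci$interval[2] >= max(gv)
  }
  attr(out, "open_lower") <- open_lo
  attr(out, "open_upper") <- open_hi
  attr(out, "ratio") <- ratio
  out
}

# re-grid free dimensions around the current optimum: same number of
# points over +/- one previous step, clipped to the original search range
local_grid <- function(cur_grid, orig_grid, opt_row, free) {
  g <- unclass(cur_grid)
  for (nm in names(g)) {
    v <- sort(unique(g[[nm]]))
    if (length(v) < 2 || !nm %in% free) next
    h <- min(diff(v))
    lo <- min(orig_grid[[nm]])
    hi <- max(orig_grid[[nm]])
    ctr <- opt_row[[nm]]
    g[[nm]] <- seq(max(lo, ctr - h), min(hi, ctr + h),
                   length.out = length(v))
  }
  structure(g, class = "sar_grid")
}

# interval where L / Lmax >= ratio, i.e. logL >= max(logL) + log(ratio);
# the connected run of scan points around the profile maximum
lr_interval <- function(values, logL, ratio = 0.9) {
  keep <- logL >= max(logL) + log(ratio)
  imax <- which.max(logL)
  lo <- imax
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- imax
  while (hi < length(keep) && keep[hi + 1]) hi <- hi + 1
  list(interval = c(values[lo], values[hi]),
       open = c(lo == 1, hi == length(keep)))
}

#' @export
plot.sar_fit <- function(x, ...) {
  d <- as.data.frame(x$data)
  f <- x$fitted
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  for (kd in c("sr", "ar")) {
    ds <- d[d$kind == kd, ]
    fs <- f[f$kind == kd & f$k <= max(ds$k), ]
    ylim <- range(0, ds$mu + ds$sigma, fs$M)
    plot(ds$k, ds$mu, pch = 8, ylim = ylim, xlab = "spike k",
         ylab = "integrated release M",
         main = if (kd == "sr") "synchronous" else "asynchronous", ...)
    arrows(ds$k, ds$mu - ds$sigma, ds$k, ds$mu + ds$sigma,
           angle = 90, code = 3, length = 0.03,
           col = adjustcolor("black", 0.5))
    lines(fs$k, fs$M, col = 2, lwd = 2)
  }
  invisible(x)
}

#' Simulate stochastic trials from a fitted SAR model
#'
#' Draws stochastic release traces at the fitted kinetic parameters. The
#' pool size `N_F` and quantum `x0` are not identified by the fit and
#' must be supplied (defaults: `N_F = 271`, `x0 = 1/N_F`, keeping the
#' fitted `X_F = 1` scale).
#'
#' @param object A `"sar_fit"`.
#' @param nsim Number of trials.
#' @param seed Base seed (trial `i` uses `seed + i - 1`).
#' @param N_F,x0 Pool structure for the quantal simulation.
#' @param ... Unused.
#' @return List of `"sar_trace"` objects.
#' @export
simulate.sar_fit <- function(object, nsim = 1, seed = 1, N_F = 271,
                             x0 = 1 / N_F, ...) {
  cf <- object$coefficients
  p <- sar_params(tau_sr = cf[["tau_sr"]], U_sr = cf[["U_sr"]],
                  tau_ar = cf[["tau_ar"]], U_ar = cf[["U_ar"]],
                  U_max = cf[["U_max"]], tau_d = cf[["tau_d"]],
                  N_F = N_F, x0 = x0, U0 = object$U0)
  sar_simulate_trials(p, object$spikes, object$T, object$dt,
                      trials = nsim, seed = seed)
}
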