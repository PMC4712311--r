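#' Quantal-size estimation from post-train asynchronous release
#'
#' Estimates the IPSC amplitude of a single released vesicle,
#' `x0~ = A * x0`, from the trial-to-trial variability of pure
#' asynchronous release after the end of a spike train. Time is divided
#' into bins of length `bin` (default 3.9 ms); within each bin `j` and
#' trial the released amount `M(j) = sum q~ dt` is computed. Treating
#' vesicle fusion in a short bin as (approximately) Poisson, `M(j)` is
#' `x0~` times a unit-Fano count, so the across-trial variance of `M(j)`
#' is `x0~` times its mean. The quantal size is therefore the slope of a
#' linear regression of per-bin variance on per-bin mean (through the
#' origin by default).
#'
#' @param trials List of release-rate tail segments, one per trial:
#'   `"release_rate"` data frames or plain numeric rate vectors of equal
#'   length (scaled rate `A q`, e.g. from [deconvolve()]); at least 2
#'   trials.
#' @param dt Sampling interval (ms) for plain numeric inputs.
#' @param bin Bin length (ms), default 3.9.
#' @param intercept Include an intercept in the regression? Default
#'   `FALSE` (through the origin).
#' @return Object of class `"quantum_fit"`: `x0_tilde` (slope, pA),
#'   `r_squared`, `n_bins`, `n_trials`, `intercept_value` (0 when
#'   through the origin), and `data` (per-bin mean and variance).
#' @examples
#' set.seed(1)
#' # Poisson quanta of size 8 pA, 60 trials, rate decaying across bins
#' tr <- replicate(60, {
#'   counts <- rpois(20, lambda = seq(4, 0.5, length.out = 20))
#'   rep(counts * 8 / 3.9, each = 78)  # rate within 3.9 ms bins, dt = 0.05
#' }, simplify = FALSE)
#' quantum_size(tr, dt = 0.05)
#' @export
quantum_size <- function(trials, dt = NULL, bin = 3.9,
                         intercept = FALSE) {
  stopifnot(is.list(trials), length(trials) >= 2, bin > 0)
  rates <- lapply(trials, function(q) {
    if (inherits(q, "release_rate")) {
      dt <<- attr(q, "dt")
      q$q_scaled_pA
    } else as.numeric(q)
  })
  if (is.null(dt)) stop("dt must be supplied for numeric inputs",
                        call. = FALSE)
  len <- unique(vapply(rates, length, 1L))
  if (length(len) != 1)
    stop("all trial segments must have equal length", call. = FALSE)
  per <- max(1L, as.integer(round(bin / dt)))
  nb <- len %/% per
  if (nb < 3) stop("fewer than 3 usable bins; supply a longer segment",
                   call. = FALSE)
  Mm <- vapply(rates, function(v) {
    m <- matrix(v[seq_len(nb * per)], nrow = per)
    colSums(m) * dt
  }, numeric(nb))                      # bins x trials
  m <- rowMeans(Mm)
  v <- apply(Mm, 1, var)
  fit <- if (intercept) lm(v ~ m) else lm(v ~ m + 0)
  slope <- unname(coef(fit)[["m"]])
  structure(list(x0_tilde = slope,
                 r_squared = summary(fit)$r.squared,
                 n_bins = nb, n_trials = length(rates),
                 intercept = intercept,
                 intercept_value = if (intercept)
                   unname(coef(fit)[["(Intercept)"]]) else 0,
                 data = data.frame(mean = m, var = v),
                 fit = fit),
            class = "quantum_fit")
}

#' @export
print.quantum_fit <- function(x, ...) {
  cat(sprintf(
    "quantal size (Fano regression): x0~ = %.3f pA  (R^2 = %.3f, %d bins, %d trials%s)\n",
    x$x0_tilde, x$r_squared, x$n_bins, x$n_trials,
    if (x$intercept) sprintf(", intercept = %.3f", x$intercept_value)
    else ", through origin"))
  invisible(x)
}

#' @export
plot.quantum_fit <- function(x, ...) {
  plot(x$data$mean, x$data$var, xlab = "per-bin mean M(j) (pA ms)",
       ylab = "per-bin variance", ...)
  abline(a = x$intercept_value, b = x$x0_tilde, col = 2, lwd = 2)
  invisible(x)
}
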