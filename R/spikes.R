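#' Regular spike trains
#'
#' @param n Number of spikes.
#' @param rate_hz Firing rate in Hz.
#' @param t0 Time of the first spike (ms).
#' @return Numeric vector of spike times in ms, strictly increasing.
#' @examples
#' regular_spikes(5, 100)  # 0, 10, 20, 30, 40 ms
#' @export
regular_spikes <- function(n, rate_hz = 100, t0 = 0) {
  stopifnot(n >= 1, rate_hz > 0)
  t0 + (seq_len(n) - 1) * 1000 / rate_hz
}

validate_spikes <- function(spikes, T = NULL) {
  if (!is.numeric(spikes) || anyNA(spikes))
    stop("spike times must be numeric and non-missing", call. = FALSE)
  if (is.unsorted(spikes, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (length(spikes) && spikes[1] < 0)
    stop("spike times must be >= 0", call. = FALSE)
  if (!is.null(T) && length(spikes) && spikes[length(spikes)] >= T)
    stop("all spikes must lie in [0, T)", call. = FALSE)
  invisible(spikes)
}

# Snap spike times to the simulation grid (0-based bin indices).
# Times must sit within dt/2 of a grid point (up to rounding noise).
snap_spikes <- function(spikes, dt, tol = NULL) {
  if (is.null(tol)) tol <- dt / 2 * (1 + 1e-8)
  idx <- round(spikes / dt)
  off <- abs(spikes - idx * dt)
  if (any(off > tol))
    stop("spike(s) at ", paste(spikes[off > tol], collapse = ", "),
         " ms are farther than dt/2 from the time grid (dt = ", dt, " ms)",
         call. = FALSE)
  as.integer(idx)
}
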