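#' Exponential receptor kernel
#'
#' Postsynaptic current model: released transmitter is convolved with a
#' single-exponential conductance kernel
#' `K(s) = A * exp(-s / tau_syn)` after a transmission delay `D`. Under
#' voltage clamp the lumped gain `A = w (v - E_rev)` is a constant, so the
#' current is linear in the release rate. The package works with release
#' magnitudes and a positive gain; the inhibitory (negative-going) sign is
#' applied only when writing IPSC-convention traces.
#'
#' @param tau_syn Conductance decay time constant (ms); ~5 ms for a GABA-A
#'   synapse from a fast-spiking interneuron onto a pyramidal cell.
#' @param A Lumped gain: current per transmitter-unit per ms. With the
#'   display convention used in the examples, a single released vesicle
#'   produces a current jump of `A * x0` (10 pA in the reference setup).
#' @param D Transmission delay (ms).
#' @return Object of class `"receptor_kernel"`.
#' @export
receptor_kernel <- function(tau_syn = 5, A = 10, D = 0.75) {
  stopifnot(tau_syn > 0, A > 0, D >= 0)
  structure(list(tau_syn = tau_syn, A = A, D = D),
            class = "receptor_kernel")
}

#' @export
print.receptor_kernel <- function(x, ...) {
  cat(sprintf("receptor kernel: tau_syn = %g ms, A = %g, D = %g ms\n",
              x$tau_syn, x$A, x$D))
  invisible(x)
}

#' Current trace container
#'
#' A uniformly sampled current trace. Current follows the IPSC convention
#' (negative-going) for `kind = "raw"`/`"leak_corrected"` traces; component
#' and reconstructed traces built from release magnitudes are positive.
#'
#' @param current_pA Current samples (pA).
#' @param dt Sampling interval (ms).
#' @param t0 Time of the first sample (ms).
#' @param kind One of `"raw"`, `"leak_corrected"`, `"reconstructed"`,
#'   `"component"`.
#' @return Data frame of class `"current_trace"` with columns `time_ms`,
#'   `current_pA` and attributes `dt`, `t0`, `kind`.
#' @export
current_trace <- function(current_pA, dt, t0 = 0, kind = "raw") {
  stopifnot(is.numeric(current_pA), all(is.finite(current_pA)), dt > 0)
  kind <- match.arg(kind, c("raw", "leak_corrected", "reconstructed",
                            "component"))
  structure(data.frame(time_ms = t0 + (seq_along(current_pA) - 1) * dt,
                       current_pA = current_pA),
            dt = dt, t0 = t0, kind = kind,
            class = c("current_trace", "data.frame"))
}

# per-bin release amounts -> rate, delayed by delta bins
shift_bins <- function(x, delta) {
  if (delta == 0) return(x)
  c(rep(0, delta), x[seq_len(length(x) - delta)])
}

#' Convolve release with the receptor kernel
#'
#' Maps per-bin released amounts to a postsynaptic current magnitude via
#' the recursive filter
#' `I(i) = I(i-1) * exp(-dt/tau_syn) + A * q(i - D/dt)`,
#' which is exactly the discrete convolution with the exponential kernel.
#'
#' @param q Per-bin released *amounts* (transmitter units per bin), e.g. a
#'   column of a [sar_simulate()] trace, or a `"sar_trace"` object (then
#'   `component` selects which release stream to use).
#' @param kernel A [receptor_kernel()].
#' @param dt Bin width in ms (taken from the trace if `q` is one).
#' @param component For a trace input: `"total"`, `"sr"` or `"ar"`.
#' @return A `"current_trace"` (positive magnitude, `kind = "component"`).
#' @examples
#' tr <- sar_simulate(sar_params(), regular_spikes(5), T = 100,
#'                    mode = "deterministic")
#' I <- release_to_current(tr, receptor_kernel())
#' max(I$current_pA)
#' @export
release_to_current <- function(q, kernel, dt = NULL,
                               component = c("total", "sr", "ar")) {
  component <- match.arg(component)
  t0 <- 0
  if (inherits(q, "sar_trace")) {
    if (!is.null(dt) && abs(dt - attr(q, "dt")) > 1e-12 * attr(q, "dt"))
      stop("dt does not match the trace sampling interval", call. = FALSE)
    dt <- attr(q, "dt")
    t0 <- attr(q, "t0")
    q <- switch(component, total = q$q_sr + q$q_ar, sr = q$q_sr, ar = q$q_ar)
  }
  if (is.null(dt)) stop("dt must be supplied for a plain numeric q",
                        call. = FALSE)
  delta <- as.integer(round(kernel$D / dt))
  if (abs(kernel$D - delta * dt) > dt * 1e-6)
    stop("kernel delay D must be a multiple of dt after snapping",
         call. = FALSE)
  qd <- shift_bins(q, delta)
  I <- as.numeric(stats::filter(kernel$A * qd, exp(-dt / kernel$tau_syn),
                                method = "recursive"))
  current_trace(I, dt, t0, kind = "component")
}

#' Split the synaptic current into synchronous and asynchronous components
#'
#' By linearity of the receptor model the total current is exactly the sum
#' of the currents driven by the synchronous and asynchronous release
#' streams.
#'
#' @param trace A `"sar_trace"` carrying separate `q_sr` and `q_ar`.
#' @param kernel A [receptor_kernel()].
#' @return List with `"current_trace"` elements `I_total`, `I_sr`, `I_ar`
#'   (`I_total = I_sr + I_ar` bin-wise).
#' @export
split_currents <- function(trace, kernel) {
  stopifnot(inherits(trace, "sar_trace"))
  I_sr <- release_to_current(trace, kernel, component = "sr")
  I_ar <- release_to_current(trace, kernel, component = "ar")
  I_total <- I_sr
  I_total$current_pA <- I_sr$current_pA + I_ar$current_pA
  list(I_total = I_total, I_sr = I_sr, I_ar = I_ar)
}
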