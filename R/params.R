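#' Parameter set of the synchronous-asynchronous release (SAR) synapse model
#'
#' Bundles the kinetic parameters of the two-sensor release model together
#' with the structural constants of the vesicle pool. The synchronous sensor
#' carries a release *probability* `u_sr` (facilitation increment `U_sr`,
#' decay `tau_sr`); the asynchronous sensor carries a release probability
#' *rate* `u_ar` in 1/ms (increment `U_ar` towards the saturation level
#' `U_max`, decay `tau_ar`). Both draw vesicles from a common
#' readily-releasable pool of at most `N_F` vesicles, each holding `x0`
#' units of transmitter (`X_F = N_F * x0`), replenished with time constant
#' `tau_d`.
#'
#' Defaults are the reference parameter set used throughout the package's
#' examples (a fast-spiking to pyramidal-cell type synapse).
#'
#' @param tau_sr Decay time constant of the synchronous release probability
#'   (ms).
#' @param U_sr Per-spike facilitation increment of `u_sr`, in `[0, 1]`.
#' @param tau_ar Decay time constant of the asynchronous release-probability
#'   rate (ms).
#' @param U_ar Per-spike facilitation increment of `u_ar` towards `U_max`,
#'   in `[0, 1]`.
#' @param U_max Saturation level of the asynchronous rate (1/ms).
#' @param tau_d Vesicle replenishment time constant (ms).
#' @param N_F Maximal number of readily-releasable vesicles (positive
#'   integer).
#' @param x0 Quantum size: transmitter content of one vesicle (> 0).
#' @param U0 Spontaneous floor of the asynchronous rate (1/ms); `u_ar`
#'   decays towards `U0`, giving spontaneous release when positive.
#'   Default 0.
#' @param D Transmission delay between release and postsynaptic current
#'   (ms). Default 0.75.
#' @return An object of class `"sar_params"` (a named list).
#' @seealso [sar_simulate()], [read_sar_params()]
#' @examples
#' p <- sar_params()
#' p
#' sar_params(tau_ar = 30, U_ar = 0.01)
#' @export
sar_params <- function(tau_sr = 2, U_sr = 0.3, tau_ar = 12, U_ar = 0.005,
                       U_max = 0.5, tau_d = 30, N_F = 271, x0 = 1,
                       U0 = 0, D = 0.75) {
  p <- list(tau_sr = tau_sr, U_sr = U_sr, tau_ar = tau_ar, U_ar = U_ar,
            U_max = U_max, tau_d = tau_d, N_F = N_F, x0 = x0, U0 = U0, D = D)
  validate_sar_params(p)
  class(p) <- "sar_params"
  p
}

validate_sar_params <- function(p) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (nm in c("tau_sr", "U_sr", "tau_ar", "U_ar", "U_max", "tau_d",
               "N_F", "x0", "U0", "D")) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite number",
                             call. = FALSE)
  }
  if (p$tau_sr <= 0 || p$tau_ar <= 0 || p$tau_d <= 0)
    stop("time constants tau_sr, tau_ar, tau_d must be strictly positive",
         call. = FALSE)
  if (p$U_sr < 0 || p$U_sr > 1) stop("U_sr must lie in [0, 1]", call. = FALSE)
  if (p$U_ar < 0 || p$U_ar > 1) stop("U_ar must lie in [0, 1]", call. = FALSE)
  if (p$U_max <= 0) stop("U_max must be > 0", call. = FALSE)
  if (p$U0 < 0 || p$U0 > p$U_max)
    stop("U0 must lie in [0, U_max]", call. = FALSE)
  if (p$N_F < 1 || p$N_F != round(p$N_F))
    stop("N_F must be a positive integer", call. = FALSE)
  if (p$x0 <= 0) stop("x0 must be > 0", call. = FALSE)
  if (p$D < 0) stop("D must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.sar_params <- function(x, ...) {
  cat("SAR synapse model parameters\n")
  cat(sprintf("  synchronous : tau_sr = %g ms, U_sr = %g\n", x$tau_sr, x$U_sr))
  cat(sprintf("  asynchronous: tau_ar = %g ms, U_ar = %g, U_max = %g /ms, U0 = %g /ms\n",
              x$tau_ar, x$U_ar, x$U_max, x$U0))
  cat(sprintf("  pool        : N_F = %d vesicles, x0 = %g, tau_d = %g ms (X_F = %g)\n",
              as.integer(x$N_F), x$x0, x$tau_d, x$N_F * x$x0))
  cat(sprintf("  delay       : D = %g ms\n", x$D))
  invisible(x)
}

#' Read / write SAR parameter sets as JSON
#'
#' The JSON object uses exactly the keys
#' `tau_sr, U_sr, tau_ar, U_ar, U_max, tau_d, N_F, x0, U0, D`
#' (units ms and 1/ms as in [sar_params()]). Missing `U0` and `D` default
#' to 0 and 0.75 ms with a message.
#'
#' @param path File path.
#' @return `read_sar_params()` returns a `"sar_params"` object;
#'   `write_sar_params()` returns `path` invisibly.
#' @export
read_sar_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("tau_sr", "U_sr", "tau_ar", "U_ar", "U_max", "tau_d",
                "N_F", "x0")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req))
    stop("parameter file '", path, "' is missing key(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  for (nm in c(required, "U0", "D")) {
    if (!is.null(raw[[nm]]) && !is.numeric(raw[[nm]]))
      stop("parameter '", nm, "' in '", path, "' is not numeric",
           call. = FALSE)
  }
  defaults <- character(0)
  if (is.null(raw$U0)) { raw$U0 <- 0; defaults <- c(defaults, "U0 = 0") }
  if (is.null(raw$D)) { raw$D <- 0.75; defaults <- c(defaults, "D = 0.75 ms") }
  if (length(defaults))
    message("applied default(s): ", paste(defaults, collapse = ", "))
  do.call(sar_params, raw[c(required, "U0", "D")])
}

#' @param params A [sar_params()] object.
#' @rdname read_sar_params
#' @export
write_sar_params <- function(params, path) {
  stopifnot(inherits(params, "sar_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
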