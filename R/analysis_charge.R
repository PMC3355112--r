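#' Integrate ON-gating charge over a time window
#'
#' Trapezoidal integral of the current over the window; with current in pA
#' and time in ms the result is in fC, with per-channel gating flux in
#' e0/ms it is in e0 units. The input is assumed baseline-corrected (model
#' currents are leak-free by construction; recorded traces should be P/8
#' subtracted first).
#'
#' @param trace A `current_trace`.
#' @param window Length-2 numeric `c(start, end)` in ms; defaults to the
#'   final (test-step) segment.
#' @return Scalar charge.
#' @export
integrate_on_charge <- function(trace, window = .step_window(trace)) {
  stopifnot(inherits(trace, "current_trace"), length(window) == 2L)
  if (window[1L] < min(trace$time) - 1e-9 ||
      window[2L] > max(trace$time) + 1e-9) {
    stop("integration window lies outside the trace", call. = FALSE)
  }
  sel <- trace$time >= window[1L] - 1e-9 & trace$time <= window[2L] + 1e-9
  trapz(trace$time[sel], trace$current[sel])
}

#' Build a Q-V curve from episodic gating-current traces
#'
#' Integrates the ON charge of every episode over the test-step window,
#' normalizes to the maximal charge, and pairs the result with the episode
#' step voltages.
#'
#' @param traces List of `current_trace` objects (>= 3 episodes).
#' @param window Integration window passed to [integrate_on_charge()];
#'   default is each trace's own test-step segment.
#' @return An object of class `qv_curve` with `voltages`, `normalized_charge`
#'   and `raw_charge`.
#' @export
build_qv <- function(traces, window = NULL) {
  stopifnot(is.list(traces), length(traces) >= 3L)
  q <- vapply(traces, function(tr) {
    integrate_on_charge(tr, if (is.null(window)) .step_window(tr) else window)
  }, numeric(1L))
  v <- vapply(traces, function(tr) as.numeric(tr$step_voltage), numeric(1L))
  qmax <- max(q)
  if (!is.finite(qmax) || qmax <= 0) {
    stop("cannot normalize Q-V: maximal charge is not positive", call. = FALSE)
  }
  structure(list(voltages = v, normalized_charge = q / qmax, raw_charge = q),
            class = "qv_curve")
}

#' @export
print.qv_curve <- function(x, ...) {
  cat(sprintf("<qv_curve> %d points, %g..%g mV\n",
              length(x$voltages), min(x$voltages), max(x$voltages)))
  invisible(x)
}

#' Apparent gating charge from a Boltzmann slope
#'
#' \eqn{z = k_B T / (\mathrm{slope} \cdot e_0)}, i.e. the thermal voltage
#' divided by the slope factor in mV.
#'
#' @param slope_k Boltzmann slope factor, mV (> 0).
#' @param pc A [physical_constants()] object.
#' @return Apparent charge in e0 units.
#' @export
charge_from_slope <- function(slope_k, pc = physical_constants()) {
  if (any(!is.finite(slope_k)) || any(slope_k <= 0)) {
    stop("`slope_k` must be positive (mV)", call. = FALSE)
  }
  pc$thermal_voltage / slope_k
}

#' Build a G-V curve from episodic ionic-current traces
#'
#' Takes the peak current magnitude of each episode within the test-step
#' window, normalizes to the maximum, and fits a single Boltzmann for the
#' activation midpoint.
#'
#' @param traces List of ionic `current_trace` objects.
#' @return An object of class `gv_curve` with `voltages`,
#'   `normalized_peak_current`, and `fit` (a `boltzmann_fit`, or NULL if
#'   fitting fails).
#' @export
build_gv <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 3L)
  pk <- vapply(traces, function(tr) {
    w <- .step_window(tr)
    sel <- tr$time >= w[1L] - 1e-9 & tr$time <= w[2L] + 1e-9
    max(abs(tr$current[sel]))
  }, numeric(1L))
  v <- vapply(traces, function(tr) as.numeric(tr$step_voltage), numeric(1L))
  if (max(pk) <= 0) {
    stop("cannot normalize G-V: all peak currents are zero", call. = FALSE)
  }
  g <- pk / max(pk)
  fit <- tryCatch(
    fit_boltzmann(structure(list(voltages = v, normalized_charge = g),
                            class = "qv_curve")),
    error = function(e) NULL)
  structure(list(voltages = v, normalized_peak_current = g, fit = fit,
                 midpoint = if (is.null(fit)) NA_real_ else fit$Q_half),
            class = "gv_curve")
}

#' @export
print.gv_curve <- function(x, ...) {
  cat(sprintf("<gv_curve> %d points, midpoint %.1f mV\n",
              length(x$voltages), x$midpoint))
  invisible(x)
}
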