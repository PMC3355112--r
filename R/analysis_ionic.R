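#' Activation delay of an ionic current (Cole-Moore measurement)
#'
#' Fits the delayed mono-exponential activation model
#' \deqn{I(t) = A\,(1 - e^{-(t - t_0)/\tau}) \quad (t \ge t_0), \qquad
#'       I(t) = 0 \quad (t < t_0)}
#' to the rising phase of an ionic current in the test-step window and
#' returns the onset \eqn{t_0} (relative to the step, clamped at >= 0) as
#' the activation delay. The Cole-Moore shift of a pair of episodes is the
#' difference of their delays (deep minus shallow prepulse); see
#' [cole_moore_shift()].
#'
#' @param trace An ionic `current_trace`.
#' @param fit_window Length-2 window (ms); defaults to the test step from
#'   its onset to the in-window peak (the rising phase).
#' @return An object of class `cole_moore_delay` with `delay` (ms, clamped),
#'   `t0_raw` (unclamped), `tau`, `amplitude`, `residual_sse` and a
#'   `negative_t0` flag.
#' @export
cole_moore_delay <- function(trace, fit_window = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  w <- .step_window(trace)
  if (is.null(fit_window)) {
    sel <- trace$time >= w[1L] - 1e-9 & trace$time <= w[2L] + 1e-9
    tt <- trace$time[sel]
    yy <- abs(trace$current[sel])
    ipk <- which.max(yy)
    fit_window <- c(w[1L], tt[ipk])
  }
  sel <- trace$time >= fit_window[1L] - 1e-9 &
    trace$time <= fit_window[2L] + 1e-9
  t <- trace$time[sel] - fit_window[1L]
  y <- abs(trace$current[sel])
  if (length(t) < 5L) stop("too few samples to fit the delay", call. = FALSE)
  a0 <- max(y)
  pred <- function(par) {
    ifelse(t < par[2L], 0, par[1L] * (1 - exp(-(t - par[2L]) / par[3L])))
  }
  sse <- function(par) {
    if (par[3L] <= 0) return(Inf)
    sum((y - pred(par))^2)
  }
  tmax <- max(t)
  starts <- list(c(a0, tmax / 20, tmax / 5), c(a0, 0, tmax / 3),
                 c(a0, tmax / 5, tmax / 5), c(a0, tmax / 10, tmax / 10))
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      stats::optim(p0, sse, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) stop("delay fit failed to converge", call. = FALSE)
  t0 <- best$par[2L]
  structure(list(delay = max(t0, 0), t0_raw = t0,
                 tau = best$par[3L], amplitude = best$par[1L],
                 residual_sse = best$value, negative_t0 = t0 < 0),
            class = "cole_moore_delay")
}

#' @export
print.cole_moore_delay <- function(x, ...) {
  cat(sprintf("<cole_moore_delay> t0 = %.3f ms (tau %.3g ms)%s\n",
              x$delay, x$tau,
              if (x$negative_t0) " [unclamped t0 < 0]" else ""))
  invisible(x)
}

#' Cole-Moore shift between two prepulse conditions
#'
#' Difference of the activation delays measured after the deepest and the
#' shallowest prepulse of a variable-prepulse protocol (delay after the
#' most hyperpolarized prepulse minus delay after the least hyperpolarized
#' one). A positive shift means stronger hyperpolarization delays
#' activation.
#'
#' @param traces List of ionic `current_trace` objects from a
#'   [make_cole_moore_protocol()] run; `step_voltage` labels carry the
#'   prepulse level.
#' @return A list of class `cole_moore_result` with `prepulses`, `delays`
#'   (ms) and `shift` (ms).
#' @export
cole_moore_shift <- function(traces) {
  stopifnot(length(traces) >= 2L)
  pre <- vapply(traces, function(tr) as.numeric(tr$step_voltage), numeric(1L))
  delays <- vapply(traces, function(tr) cole_moore_delay(tr)$delay,
                   numeric(1L))
  deep <- which.min(pre)
  shallow <- which.max(pre)
  structure(list(prepulses = pre, delays = delays,
                 shift = delays[deep] - delays[shallow]),
            class = "cole_moore_result")
}

#' @export
print.cole_moore_result <- function(x, ...) {
  cat(sprintf("<cole_moore_result> shift = %.3f ms (prepulses %s mV)\n",
              x$shift, paste(x$prepulses, collapse = ", ")))
  invisible(x)
}
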