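# Exponential decay fitting of gating currents, tau-V curves and
# trace-crossing detection.

# single- or double-exponential SSE fits on (t, y); t relative to window
# start, y assumed decaying toward 0
.fit_exp1 <- function(t, y) {
  ypos <- pmax(abs(y), max(abs(y)) * 1e-6)
  lmfit <- stats::lm(log(ypos) ~ t)
  tau0 <- -1 / min(stats::coef(lmfit)[2L], -1e-6)
  a0 <- y[1L]
  sse <- function(par) sum((y - par[1L] * exp(-t / par[2L]))^2)
  best <- .multistart_optim(
    list(c(a0, tau0), c(a0, tau0 / 3), c(a0, tau0 * 3),
         c(a0, max(t) / 3)),
    sse, lower = c(-Inf, 1e-6), upper = c(Inf, Inf))
  list(A = best$par[1L], tau = best$par[2L], sse = best$value)
}

.fit_exp2 <- function(t, y, f1) {
  sse <- function(par) {
    sum((y - par[1L] * exp(-t / par[2L]) - par[3L] * exp(-t / par[4L]))^2)
  }
  starts <- list(
    c(f1$A / 2, f1$tau / 3, f1$A / 2, f1$tau * 3),
    c(f1$A * 0.8, f1$tau, f1$A * 0.2, f1$tau * 5),
    c(f1$A * 0.2, f1$tau / 5, f1$A * 0.8, f1$tau),
    c(f1$A / 2, f1$tau / 10, f1$A / 2, f1$tau))
  best <- .multistart_optim(starts, sse,
                            lower = c(-Inf, 1e-6, -Inf, 1e-6),
                            upper = c(Inf, Inf, Inf, Inf))
  p <- best$par
  if (p[2L] > p[4L]) p <- p[c(3L, 4L, 1L, 2L)]  # order tau ascending
  list(A = p[c(1L, 3L)], tau = p[c(2L, 4L)], sse = best$value)
}

#' Fit the decay of a gating current and report the weighted time constant
#'
#' Fits single- and double-exponential decays to the current in the fit
#' window (default: from the in-window peak of the absolute current to the
#' end of the test step, the region where ON-gating currents relax) and
#' keeps the double-exponential model only if it improves the SSE by more
#' than a relative threshold. The summary statistic is the
#' amplitude-weighted time constant
#' \eqn{\tau_w = \sum A_i \tau_i / \sum A_i}.
#'
#' @param trace A `current_trace`.
#' @param fit_window Length-2 window (ms); defaults to peak-to-end of the
#'   test step.
#' @param improvement_threshold Relative SSE improvement required to accept
#'   the two-component model (default 0.05 = 5 percent).
#' @return An object of class `decay_fit` with `amplitudes`, `taus` (ms),
#'   `weighted_tau` (ms) and `n_components`.
#' @export
fit_decay <- function(trace, fit_window = NULL,
                      improvement_threshold = 0.05) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(fit_window)) {
    w <- .step_window(trace)
    sel <- trace$time >= w[1L] - 1e-9 & trace$time <= w[2L] + 1e-9
    tt <- trace$time[sel]
    yy <- trace$current[sel]
    ipk <- which.max(abs(yy))
    fit_window <- c(tt[ipk], w[2L])
  }
  if (fit_window[1L] < min(trace$time) - 1e-9 ||
      fit_window[2L] > max(trace$time) + 1e-9 ||
      fit_window[1L] >= fit_window[2L]) {
    stop("invalid decay fit window", call. = FALSE)
  }
  sel <- trace$time >= fit_window[1L] - 1e-9 &
    trace$time <= fit_window[2L] + 1e-9
  t <- trace$time[sel] - fit_window[1L]
  y <- trace$current[sel]
  if (length(t) < 5L) stop("too few samples in the fit window", call. = FALSE)

  f1 <- .fit_exp1(t, y)
  f2 <- tryCatch(.fit_exp2(t, y, f1), error = function(e) NULL)
  use2 <- !is.null(f2) &&
    f2$sse < (1 - improvement_threshold) * f1$sse &&
    all(f2$A * sign(sum(f2$A)) > 0)   # reject sign-flipped pairs
  if (use2) {
    amps <- f2$A
    taus <- f2$tau
  } else {
    amps <- f1$A
    taus <- f1$tau
  }
  structure(list(amplitudes = amps, taus = taus,
                 weighted_tau = sum(abs(amps) * taus) / sum(abs(amps)),
                 n_components = length(taus),
                 residual_sse = if (use2) f2$sse else f1$sse,
                 fit_window = fit_window),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %d component(s), tau = %s ms, tau_w = %.3g ms\n",
              x$n_components,
              paste(sprintf("%.3g", x$taus), collapse = ", "),
              x$weighted_tau))
  invisible(x)
}

#' Weighted decay time constant as a function of step voltage
#'
#' Applies [fit_decay()] to every episode and returns the tau-V relation,
#' with local maxima located (interior points larger than both neighbours).
#'
#' @param traces List of `current_trace` objects.
#' @param ... Passed to [fit_decay()].
#' @return A list with `voltages`, `weighted_tau` (ms) and `local_maxima`
#'   (voltages of interior local maxima).
#' @export
tau_voltage_curve <- function(traces, ...) {
  v <- vapply(traces, function(tr) as.numeric(tr$step_voltage), numeric(1L))
  tw <- vapply(traces, function(tr) fit_decay(tr, ...)$weighted_tau,
               numeric(1L))
  o <- order(v)
  v <- v[o]
  tw <- tw[o]
  n <- length(v)
  is_max <- rep(FALSE, n)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      is_max[i] <- tw[i] > tw[i - 1L] && tw[i] > tw[i + 1L]
    }
  }
  list(voltages = v, weighted_tau = tw, local_maxima = v[is_max])
}

#' Detect post-peak crossings between consecutive episodes
#'
#' For every consecutive pair of episodes (ordered by step voltage) the
#' difference of the two currents is examined after both peaks; a sign
#' change of the difference there means the trace evoked by the stronger
#' depolarization crosses the weaker one during the decay. Tiny sign
#' changes below `tol` times the pair's peak amplitude are ignored, and so
#' are flips inside the first `settle_ms` after the later peak: in a
#' channel with one fast and one slow charge component the difference is
#' briefly biphasic while the fast component equilibrates, which is not
#' the decay crossover of interest.
#'
#' @param traces List of `current_trace` objects sharing a time grid.
#' @param tol Relative amplitude tolerance for a genuine crossing.
#' @param settle_ms Dead time after the peaks before crossings count, ms.
#' @return A data frame with `v_low`, `v_high`, `crossing` (logical) and
#'   `t_cross` (ms, NA when none).
#' @export
detect_crossings <- function(traces, tol = 1e-3, settle_ms = 2) {
  stopifnot(length(traces) >= 2L)
  v <- vapply(traces, function(tr) as.numeric(tr$step_voltage), numeric(1L))
  o <- order(v)
  traces <- traces[o]
  v <- v[o]
  out <- data.frame(v_low = v[-length(v)], v_high = v[-1L],
                    crossing = FALSE, t_cross = NA_real_)
  for (i in seq_len(length(traces) - 1L)) {
    a <- traces[[i]]
    b <- traces[[i + 1L]]
    if (length(a$time) != length(b$time) ||
        max(abs(a$time - b$time)) > 1e-9) {
      stop("episodes must share a time grid", call. = FALSE)
    }
    w <- .step_window(a)
    sel <- a$time >= w[1L] - 1e-9 & a$time <= w[2L] + 1e-9
    tt <- a$time[sel]
    ya <- a$current[sel]
    yb <- b$current[sel]
    t_peak <- max(tt[which.max(abs(ya))], tt[which.max(abs(yb))])
    post <- tt > t_peak + settle_ms
    if (sum(post) < 3L) next
    d <- yb[post] - ya[post]
    thr <- tol * max(abs(ya), abs(yb))
    sgn <- sign(d) * (abs(d) > thr)
    sgn_nz <- sgn[sgn != 0]
    if (length(sgn_nz) >= 2L && any(diff(sgn_nz) != 0)) {
      out$crossing[i] <- TRUE
      flip <- which(diff(sign(d)) != 0)[1L]
      out$t_cross[i] <- tt[post][flip]
    }
  }
  out
}
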