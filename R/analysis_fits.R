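# Boltzmann fitting of Q-V / G-V curves.
#
# All fitters are deterministic: least squares minimized with L-BFGS-B from
# a fixed multistart grid (7 candidate midpoints spanning the voltage range
# crossed with 7 log-spaced slope factors), best SSE wins, ties broken by
# grid order. Asymptotes are constrained to 0 and 1 (curves are normalized
# charge), so a fitted curve always passes through 0.5 at its midpoint.

.fit_sse_optim <- function(par0, fn, lower, upper) {
  res <- tryCatch(
    stats::optim(par0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 200L, factr = 1e7)),
    error = function(e) NULL)
  res
}

.multistart_optim <- function(starts, fn, lower, upper) {
  best <- NULL
  for (p0 in starts) {
    res <- .fit_sse_optim(p0, fn, lower, upper)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-15) best <- res
  }
  if (is.null(best)) stop("fit failed to converge from any start",
                          call. = FALSE)
  best
}

#' Fit a single Boltzmann function to a Q-V curve
#'
#' Least-squares fit of \eqn{y = 1/(1+\exp(-(V-Q_{1/2})/k))} with
#' asymptotes constrained to 0 and 1.
#'
#' @param qv A `qv_curve` (or any list with `voltages` and
#'   `normalized_charge`).
#' @return An object of class `boltzmann_fit` with `Q_half`, `slope_k`
#'   (mV), `amplitude` (fixed at 1) and `residual_sse`.
#' @export
fit_boltzmann <- function(qv) {
  v <- qv$voltages
  y <- qv$normalized_charge
  stopifnot(length(v) == length(y))
  if (length(v) < 4L) stop("need at least 4 points", call. = FALSE)
  if (max(y) - min(y) < 0.05) {
    stop("degenerate Q-V: no transition in the data (slope unidentifiable)",
         call. = FALSE)
  }
  sse <- function(par) sum((y - boltzmann(v, par[1L], par[2L]))^2)
  vr <- range(v)
  q_grid <- seq(vr[1L], vr[2L], length.out = 7L)
  k_grid <- exp(seq(log(1), log(40), length.out = 7L))
  starts <- lapply(seq_len(49L), function(i) {
    c(q_grid[(i - 1L) %/% 7L + 1L], k_grid[(i - 1L) %% 7L + 1L])
  })
  best <- .multistart_optim(starts, sse,
                            lower = c(vr[1L] - 100, 0.5),
                            upper = c(vr[2L] + 100, 200))
  structure(list(Q_half = best$par[1L], slope_k = best$par[2L],
                 amplitude = 1.0, residual_sse = best$value),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> Q1/2 = %.2f mV, k = %.2f mV, SSE = %.3g\n",
              x$Q_half, x$slope_k, x$residual_sse))
  invisible(x)
}

#' Fit a double (two-component) Boltzmann function to a Q-V curve
#'
#' Least-squares fit of the mixture
#' \eqn{y = A\,B_1(V) + (1-A)\,B_2(V)} of two unit Boltzmann terms sharing
#' the 0/1 asymptotes. After fitting, the components are ordered so that
#' `Q_half_1 < Q_half_2` (label switching resolved by swapping and
#' replacing A with 1 - A). The multistart grid includes the single
#' Boltzmann solution split by +/- 40 mV, the classic initialization for
#' resolving a shoulder component.
#'
#' @param qv A `qv_curve`.
#' @return An object of class `double_boltzmann_fit` with `fraction_1`,
#'   `Q_half_1`, `slope_k_1`, `Q_half_2`, `slope_k_2`, `residual_sse` and a
#'   logical `fraction_at_bound` flag (fraction pinned at its box bound,
#'   i.e. one component unidentifiable).
#' @export
fit_double_boltzmann <- function(qv) {
  v <- qv$voltages
  y <- qv$normalized_charge
  stopifnot(length(v) == length(y))
  if (length(v) < 6L) stop("need at least 6 points", call. = FALSE)
  single <- fit_boltzmann(qv)
  model <- function(par) {
    par[1L] * boltzmann(v, par[2L], par[3L]) +
      (1 - par[1L]) * boltzmann(v, par[4L], par[5L])
  }
  sse <- function(par) sum((y - model(par))^2)
  vr <- range(v)
  lo <- c(1e-3, vr[1L] - 100, 0.5, vr[1L] - 100, 0.5)
  hi <- c(1 - 1e-3, vr[2L] + 100, 200, vr[2L] + 100, 200)
  starts <- list()
  for (a in c(0.1, 0.2, 0.3, 0.5)) {
    for (dv in c(20, 40, 70)) {
      starts[[length(starts) + 1L]] <-
        c(a, single$Q_half - dv, single$slope_k,
          single$Q_half + dv, single$slope_k)
      starts[[length(starts) + 1L]] <-
        c(a, single$Q_half - 2 * dv, 2 * single$slope_k,
          single$Q_half, single$slope_k)
    }
  }
  best <- .multistart_optim(starts, sse, lower = lo, upper = hi)
  p <- best$par
  if (p[2L] > p[4L]) {               # enforce Q_half_1 < Q_half_2
    p <- c(1 - p[1L], p[4L], p[5L], p[2L], p[3L])
  }
  at_bound <- p[1L] <= lo[1L] + 1e-9 || p[1L] >= hi[1L] - 1e-9
  structure(list(fraction_1 = p[1L],
                 Q_half_1 = p[2L], slope_k_1 = p[3L],
                 Q_half_2 = p[4L], slope_k_2 = p[5L],
                 residual_sse = best$value,
                 fraction_at_bound = at_bound),
            class = "double_boltzmann_fit")
}

#' @export
print.double_boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<double_boltzmann_fit> A1 = %.3f: Q1/2 = %.1f mV (k %.2f); ",
           "Q1/2 = %.1f mV (k %.2f); SSE = %.3g%s\n"),
    x$fraction_1, x$Q_half_1, x$slope_k_1, x$Q_half_2, x$slope_k_2,
    x$residual_sse,
    if (x$fraction_at_bound) " [fraction at bound]" else ""))
  invisible(x)
}
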