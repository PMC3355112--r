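# shared numeric helpers

#' Unit Boltzmann function
#'
#' \eqn{y(V) = 1/(1 + \exp(-(V - V_{1/2})/k))}, the canonical sigmoid used
#' for Q-V and G-V curves.
#'
#' @param V Voltage, mV (vectorized).
#' @param V_half Midpoint, mV.
#' @param slope_k Slope factor, mV (> 0 for activation).
#' @return Values in (0, 1).
#' @export
boltzmann <- function(V, V_half, slope_k) {
  1 / (1 + exp(-(V - V_half) / slope_k))
}

# trapezoidal quadrature on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# index of the sample window covering the final (test-step) segment
.step_window <- function(trace) {
  if (is.null(trace$segments)) {
    return(range(trace$time))
  }
  n <- nrow(trace$segments)
  c(trace$segments$start[n], trace$segments$end[n])
}
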