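#' Piecewise-constant voltage-command protocol
#'
#' An episodic stimulation protocol: every episode (sweep) is an ordered list
#' of constant-voltage segments delivered from a common holding potential.
#' Sampling convention: samples sit on a uniform grid starting at the first
#' segment's onset, both endpoints included, and a segment boundary shares a
#' sample with the following segment (the sample at a boundary is attributed
#' to the incoming segment, whose rates already apply there). Segment
#' durations must therefore be integer multiples of `sample_interval`.
#'
#' @param episodes List of data frames, one per episode, each with columns
#'   `duration` (ms) and `voltage` (mV).
#' @param holding_potential Holding potential, mV; initial conditions are
#'   equilibrium at this voltage.
#' @param sample_interval Sampling interval, ms.
#' @param episode_labels Numeric label per episode (e.g. the step voltage).
#'
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(episodes, holding_potential,
                             sample_interval = 0.1,
                             episode_labels = seq_along(episodes)) {
  stopifnot(is.list(episodes), length(episodes) >= 1L,
            length(episode_labels) == length(episodes))
  if (!is.finite(sample_interval) || sample_interval <= 0) {
    stop("`sample_interval` must be > 0 (ms)", call. = FALSE)
  }
  for (ep in episodes) {
    stopifnot(is.data.frame(ep), all(c("duration", "voltage") %in% names(ep)))
    if (any(ep$duration <= 0)) {
      stop("all segment durations must be > 0 (ms)", call. = FALSE)
    }
    if (sample_interval > min(ep$duration) + 1e-12) {
      stop("`sample_interval` must not exceed the shortest segment",
           call. = FALSE)
    }
    n_dt <- ep$duration / sample_interval
    if (any(abs(n_dt - round(n_dt)) > 1e-8)) {
      stop("segment durations must be integer multiples of `sample_interval`",
           call. = FALSE)
    }
  }
  structure(list(episodes = episodes,
                 holding_potential = holding_potential,
                 sample_interval = sample_interval,
                 episode_labels = episode_labels),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "<voltage_protocol> %d episodes, holding %.0f mV, dt = %g ms\n",
    length(x$episodes), x$holding_potential, x$sample_interval))
  cat(sprintf("  labels: %s\n", paste(x$episode_labels, collapse = ", ")))
  invisible(x)
}

#' Number of episodes in a protocol
#' @param prot A [voltage_protocol()].
#' @return Integer count.
#' @export
n_episodes <- function(prot) length(prot$episodes)

# uniform sample grid of one episode (t = 0 at first segment onset)
episode_time_grid <- function(prot, episode) {
  ep <- prot$episodes[[episode]]
  dt <- prot$sample_interval
  seq(0, sum(ep$duration), by = dt)
}

# voltage at each sample of the grid; boundary samples take the incoming
# (later) segment's voltage, matching the rate convention in the propagator
episode_voltage_at <- function(prot, episode, times) {
  ep <- prot$episodes[[episode]]
  ends <- cumsum(ep$duration)
  starts <- c(0, ends[-length(ends)])
  V <- numeric(length(times))
  for (s in seq_len(nrow(ep))) {
    sel <- times >= starts[s] - 1e-9 & times < ends[s] - 1e-9
    V[sel] <- ep$voltage[s]
  }
  V[times >= ends[length(ends)] - 1e-9] <- ep$voltage[nrow(ep)]
  V
}

#' Standard ON-gating step protocol
#'
#' One episode per step voltage: a prepulse segment followed by a
#' depolarizing test step, run from a common holding potential. Defaults
#' reproduce the canonical gating protocol: 60 ms steps from -140 to +40 mV
#' in 10 mV increments after a 20 ms prepulse to -140 mV, from a holding
#' potential of -100 mV.
#'
#' Every episode opens with a settle segment at the holding potential
#' (occupancies are stationary there, and it provides the baseline region
#' used by P/8 alignment), then the prepulse, then the test step.
#'
#' @param start,stop,increment Step-voltage range and increment, mV.
#' @param step_ms Test-step duration, ms.
#' @param prepulse_mV,prepulse_ms Prepulse level (mV) and duration (ms).
#' @param holding_mV Holding potential, mV.
#' @param holding_ms Duration of the recorded settle segment at holding, ms.
#' @param sample_interval_ms Sampling interval, ms (default 0.1 = 10 kHz).
#' @return A [voltage_protocol()]; episode labels are the step voltages.
#' @export
make_gating_protocol <- function(start = -140, stop = 40, increment = 10,
                                 step_ms = 60, prepulse_mV = -140,
                                 prepulse_ms = 20, holding_mV = -100,
                                 holding_ms = 10,
                                 sample_interval_ms = 0.1) {
  if (!is.finite(increment) || increment <= 0) {
    stop("`increment` must be > 0", call. = FALSE)
  }
  if (start > stop) stop("`start` must be <= `stop`", call. = FALSE)
  steps <- seq(start, stop, by = increment)
  eps <- lapply(steps, function(v) {
    data.frame(duration = c(holding_ms, prepulse_ms, step_ms),
               voltage = c(holding_mV, prepulse_mV, v))
  })
  voltage_protocol(eps, holding_potential = holding_mV,
                   sample_interval = sample_interval_ms,
                   episode_labels = steps)
}

#' Cole-Moore (variable prepulse) protocol
#'
#' One episode per prepulse level, each followed by an identical test step.
#' Episode labels carry the prepulse voltage.
#'
#' @param prepulse_mVs Two or more prepulse levels, mV (a single level is
#'   allowed for controls).
#' @param prepulse_ms Prepulse duration, ms.
#' @param test_mV,test_ms Test-step level (mV) and duration (ms).
#' @param holding_mV Holding potential, mV.
#' @param holding_ms Duration of the recorded settle segment at holding, ms.
#' @param sample_interval_ms Sampling interval, ms.
#' @return A [voltage_protocol()].
#' @export
make_cole_moore_protocol <- function(prepulse_mVs = c(-140, -60),
                                     prepulse_ms = 100, test_mV = 0,
                                     test_ms = 60, holding_mV = -100,
                                     holding_ms = 10,
                                     sample_interval_ms = 0.1) {
  if (length(prepulse_mVs) < 1L) {
    stop("need at least one prepulse level", call. = FALSE)
  }
  eps <- lapply(prepulse_mVs, function(v) {
    data.frame(duration = c(holding_ms, prepulse_ms, test_ms),
               voltage = c(holding_mV, v, test_mV))
  })
  voltage_protocol(eps, holding_potential = holding_mV,
                   sample_interval = sample_interval_ms,
                   episode_labels = prepulse_mVs)
}
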