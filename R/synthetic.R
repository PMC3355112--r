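#' Acquisition noise/filter model for synthetic recordings
#'
#' Describes the recording chain emulated by [generate_recording()]: white
#' Gaussian current noise of a given RMS amplitude added at the acquisition
#' sample rate, then a causal 4-pole Bessel-type low-pass filter (the
#' standard patch-clamp anti-alias filter), then decimation to the
#' protocol's sampling interval.
#'
#' @param rms_noise RMS of the white noise before filtering, pA (>= 0).
#' @param filter_cutoff Low-pass -3 dB cutoff, kHz; `NULL` disables the
#'   filter (an idealized infinite-bandwidth recording).
#' @param sample_rate Acquisition (pre-decimation) sample rate, kHz; must be
#'   at least twice the cutoff.
#' @param seed Integer seed from which all randomness of a recording flows.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rms_noise = 2, filter_cutoff = 1, sample_rate = 50,
                        seed = 1L) {
  if (rms_noise < 0) stop("`rms_noise` must be >= 0", call. = FALSE)
  if (!is.null(filter_cutoff) && filter_cutoff > sample_rate / 2) {
    stop("`filter_cutoff` must not exceed half the sample rate",
         call. = FALSE)
  }
  structure(list(rms_noise = rms_noise, filter_cutoff = filter_cutoff,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "noise_model")
}

# Two second-order sections of the 4th-order Bessel low-pass prototype
# (poles normalized so the analog filter is -3 dB at omega = 1), mapped to
# digital biquads by the bilinear transform with frequency prewarping.
# Coefficients returned as list(b = c(b0,b1,b2), a = c(1,a1,a2)) per section.
bessel4_coefficients <- function(cutoff_khz, sample_rate_khz) {
  if (cutoff_khz <= 0 || cutoff_khz >= sample_rate_khz / 2) {
    stop("cutoff must lie in (0, sample_rate/2)", call. = FALSE)
  }
  poles <- list(complex(real = -1.3700678305514395,
                        imaginary = 0.4102497174937738),
                complex(real = -0.9952087643502354,
                        imaginary = 1.2571057394546699))
  cc <- 1 / tan(pi * cutoff_khz / sample_rate_khz)  # prewarped map constant
  lapply(poles, function(p) {
    w2 <- Mod(p)^2        # omega0^2 of the section
    tz <- -2 * Re(p)      # 2*zeta*omega0
    a0 <- cc^2 + tz * cc + w2
    list(b = w2 * c(1, 2, 1) / a0,
         a = c(1, (-2 * cc^2 + 2 * w2) / a0, (cc^2 - tz * cc + w2) / a0))
  })
}

.apply_biquad <- function(x, sec) {
  # steady-state initialization: remove the initial level, filter the
  # deviation with zero state, add the level back (DC gain is 1)
  x0 <- x[1L]
  xz <- c(0, 0, x - x0)
  v <- stats::filter(xz, sec$b, method = "convolution", sides = 1)
  v <- v[-(1:2)]
  v[is.na(v)] <- 0
  y <- stats::filter(v, -sec$a[2:3], method = "recursive")
  as.numeric(y) + x0
}

#' Causal 4-pole Bessel-type low-pass filter
#'
#' Applies the two cascaded biquad sections of [bessel4_coefficients()].
#' Unit DC gain, -3 dB at the cutoff, near-monotone step response
#' (overshoot below one percent, the Bessel characteristic).
#'
#' @param x Numeric signal sampled at `sample_rate_khz`.
#' @param cutoff_khz -3 dB cutoff frequency, kHz.
#' @param sample_rate_khz Sample rate, kHz.
#' @return Filtered signal, same length as `x`.
#' @export
bessel4_filter <- function(x, cutoff_khz, sample_rate_khz) {
  secs <- bessel4_coefficients(cutoff_khz, sample_rate_khz)
  .apply_biquad(.apply_biquad(x, secs[[1L]]), secs[[2L]])
}

#' Add linear leak and capacitive transients to a trace
#'
#' Adds the two linear artifact components of a whole-cell recording: an
#' ohmic leak \eqn{g_{leak}(V(t) - E_{leak})} and, at every voltage step of
#' amplitude \eqn{\Delta V} (including the initial step off the holding
#' potential), a relaxing capacitive transient
#' \eqn{C\,\Delta V/\tau_s \; e^{-(t-t_{step})/\tau_s}} whose integral is
#' the capacitive charge \eqn{C\,\Delta V}.
#'
#' @param trace A `current_trace` in pA carrying its `segments` table and a
#'   `holding` entry in its metadata.
#' @param leak_conductance Leak conductance, nS.
#' @param leak_reversal Leak reversal potential, mV.
#' @param cap Membrane/pipette capacitance, pF.
#' @param series_tau Clamp charging time constant, ms.
#' @return The trace with artifacts added.
#' @export
add_leak_and_capacitance <- function(trace, leak_conductance = 0,
                                     leak_reversal = 0, cap = 0,
                                     series_tau = 0.5) {
  stopifnot(inherits(trace, "current_trace"), !is.null(trace$segments))
  seg <- trace$segments
  holding <- trace$metadata$holding
  if (is.null(holding)) holding <- seg$voltage[1L]
  t <- trace$time
  V <- numeric(length(t))
  for (s in seq_len(nrow(seg))) {
    V[t >= seg$start[s] - 1e-9] <- seg$voltage[s]
  }
  i_art <- leak_conductance * (V - leak_reversal)
  v_prev <- c(holding, seg$voltage[-nrow(seg)])
  if (cap > 0) {
    for (s in seq_len(nrow(seg))) {
      dv <- seg$voltage[s] - v_prev[s]
      if (dv == 0) next
      on <- t >= seg$start[s] - 1e-9
      i_art[on] <- i_art[on] +
        cap * dv / series_tau * exp(-(t[on] - seg$start[s]) / series_tau)
    }
  }
  trace$current <- trace$current + i_art
  trace$metadata$leak <- list(g = leak_conductance, E = leak_reversal,
                              cap = cap, series_tau = series_tau)
  trace
}

#' P/8 leak and capacitance subtraction
#'
#' Subtracts the summed response of eight scaled subthreshold pulses from a
#' raw episode. The subpulses span one eighth of the test episode's voltage
#' excursion each, so their sum equals the linear (leak + capacitive)
#' response of the full excursion and cancels it exactly; any nonlinear
#' gating component evoked by the small subpulses contaminates the
#' correction, exactly as in a real recording.
#'
#' @param raw A raw `current_trace`.
#' @param subpulses List of eight subpulse `current_trace`s on the same
#'   time grid.
#' @return The corrected `current_trace`.
#' @export
p_over_8_subtract <- function(raw, subpulses) {
  stopifnot(inherits(raw, "current_trace"), length(subpulses) >= 1L)
  # baseline-align every sweep to its initial (pre-excursion) segment, as
  # acquisition software does, so each trace's holding-level leak drops out
  align <- function(tr) {
    sel <- if (!is.null(tr$segments)) {
      tr$time <= tr$segments$end[1L] + 1e-9
    } else {
      seq_len(max(2L, length(tr$time) %/% 10L))
    }
    tr$current - mean(tr$current[sel])
  }
  total <- numeric(length(raw$time))
  for (sp in subpulses) {
    if (length(sp$time) != length(raw$time) ||
        max(abs(sp$time - raw$time)) > 1e-9) {
      stop("subpulse grids do not match the raw trace", call. = FALSE)
    }
    total <- total + align(sp)
  }
  raw$current <- align(raw) - total
  raw$metadata$subtracted <- "P/8"
  raw
}

# internal: charge-conserving sampling of the gating flux. The recorded
# current of sample k is the average flux over [t_k, t_k+1), i.e. the
# displaced charge difference divided by the sample interval. Unlike
# instantaneous flux sampling this is exact for arbitrarily stiff
# relaxations (the sub-sample spike at a saturating step carries its true
# area), emulating an integrating anti-alias acquisition chain.
.gating_avg_trace <- function(traj, space, asm, scale = c("pA", "e0_per_ms")) {
  scale <- match.arg(scale)
  q_t <- as.numeric(traj$probabilities %*% space$state_charge)
  dt <- traj$time[2L] - traj$time[1L]
  iq <- diff(q_t) / dt
  iq <- c(iq, iq[length(iq)])
  units <- "e0/ms"
  if (scale == "pA") {
    iq <- iq * asm$n_channels * .E0_FC
    units <- "pA"
  }
  current_trace(traj$time, iq, traj$episode_label, "gating", units,
                segments = traj$segments,
                metadata = list(scale = scale, sampling = "averaged",
                                n_channels = asm$n_channels,
                                holding = traj$holding_potential))
}

# internal: fine-grid copy of a protocol for acquisition-rate simulation
.fine_protocol <- function(prot, sample_rate_khz) {
  dt_fine <- 1 / sample_rate_khz
  ratio <- prot$sample_interval / dt_fine
  if (abs(ratio - round(ratio)) > 1e-8 || ratio < 1 - 1e-8) {
    stop(paste("acquisition sample rate must be an integer multiple of the",
               "protocol sampling rate"), call. = FALSE)
  }
  fine <- prot
  fine$sample_interval <- dt_fine
  list(prot = fine, decim = as.integer(round(ratio)))
}

#' Generate a synthetic patch-clamp recording
#'
#' The stand-in for raw experimental data: deterministic model currents are
#' simulated at the acquisition sample rate, leak and capacitive artifacts
#' are added, Gaussian noise is applied, everything passes through the
#' causal Bessel-type low-pass filter, and the result is decimated to the
#' protocol's sampling interval. With `p8_subtract = TRUE`, eight noisy
#' subpulse episodes are generated per test episode (1/8 voltage excursions
#' from `p8_holding`, same artifact parameters, same filter) and subtracted.
#' The returned object carries the full generating ground truth; rebuilding
#' with the same seed is bit-identical.
#'
#' @param asm A [channel_assembly()] (the population scale comes from its
#'   `n_channels`).
#' @param prot A [voltage_protocol()].
#' @param noise A [noise_model()].
#' @param pc A [physical_constants()] object.
#' @param kind `"gating"` or `"ionic"`.
#' @param leak_conductance,leak_reversal,cap,series_tau Artifact parameters,
#'   see [add_leak_and_capacitance()]; defaults add nothing.
#' @param p8_subtract Apply P/8 subtraction (implies artifacts are worth
#'   removing).
#' @param p8_holding Holding level of the subpulse train, mV.
#' @param antialias Use charge-conserving (sample-averaged) sampling of the
#'   gating flux (default), which keeps the area of sub-sample relaxation
#'   spikes exact at any acquisition rate, as an integrating anti-alias
#'   stage does; `FALSE` samples the instantaneous flux exactly as
#'   [gating_current_trace()] reports it.
#' @param replicates Number of replicate recordings. The deterministic
#'   simulation is shared; replicate i draws its noise from `seed + i - 1`,
#'   so replicate 1 of a batch equals a single-recording call.
#' @return An object of class `synthetic_recording` with `traces` (pA, on
#'   the protocol grid), `ground_truth` and `subtracted`; with
#'   `replicates > 1`, a list of such objects.
#' @export
generate_recording <- function(asm, prot, noise = noise_model(),
                               pc = physical_constants(),
                               kind = c("gating", "ionic"),
                               leak_conductance = 0, leak_reversal = 0,
                               cap = 0, series_tau = 0.5,
                               p8_subtract = FALSE,
                               p8_holding = prot$holding_potential,
                               antialias = TRUE,
                               replicates = 1L) {
  kind <- match.arg(kind)
  fp <- .fine_protocol(prot, noise$sample_rate)
  fine <- fp$prot
  decim <- fp$decim
  space <- build_state_space(asm)

  sim_episode <- function(p, i) {
    traj <- propagate_occupancy(asm, p, i, pc, space)
    tr <- if (kind == "gating" && antialias) {
      .gating_avg_trace(traj, space, asm, scale = "pA")
    } else if (kind == "gating") {
      gating_current_trace(traj, space, asm, pc, scale = "pA")
    } else {
      ionic_current_trace(traj, asm, pc)
    }
    add_leak_and_capacitance(tr, leak_conductance, leak_reversal,
                             cap, series_tau)
  }
  corrupt <- function(tr) {
    x <- tr$current
    if (noise$rms_noise > 0) {
      x <- x + stats::rnorm(length(x), sd = noise$rms_noise)
    }
    if (!is.null(noise$filter_cutoff)) {
      x <- bessel4_filter(x, noise$filter_cutoff, noise$sample_rate)
    }
    tr$current <- x
    tr
  }
  decimate <- function(tr) {
    keep <- seq(1L, length(tr$time), by = decim)
    tr$time <- tr$time[keep]
    tr$current <- tr$current[keep]
    tr
  }
  subpulse_protocol <- function(i) {
    ep <- fine$episodes[[i]]
    sub <- ep
    sub$voltage <- p8_holding + (ep$voltage - prot$holding_potential) / 8
    voltage_protocol(list(sub), holding_potential = p8_holding,
                     sample_interval = fine$sample_interval,
                     episode_labels = fine$episode_labels[i])
  }

  # deterministic (noise-free) parts, computed once and shared by replicates
  det <- lapply(seq_len(n_episodes(fine)), function(i) sim_episode(fine, i))
  det_subs <- if (p8_subtract) {
    lapply(seq_len(n_episodes(fine)), function(i) {
      sim_episode(subpulse_protocol(i), 1L)
    })
  } else NULL

  one_recording <- function(seed_i) {
    nm_i <- noise
    nm_i$seed <- as.integer(seed_i)
    traces <- with_preserved_seed(seed_i, {
      lapply(seq_along(det), function(i) {
        raw <- corrupt(det[[i]])
        if (p8_subtract) {
          subs <- lapply(1:8, function(j) corrupt(det_subs[[i]]))
          raw <- p_over_8_subtract(raw, subs)
        }
        decimate(raw)
      })
    })
    structure(list(
      traces = traces,
      ground_truth = list(assembly = asm, noise = nm_i, kind = kind,
                          leak = list(g = leak_conductance,
                                      E = leak_reversal,
                                      cap = cap, series_tau = series_tau),
                          p8_subtract = p8_subtract,
                          p8_holding = p8_holding,
                          holding = prot$holding_potential),
      subtracted = p8_subtract), class = "synthetic_recording")
  }

  if (replicates == 1L) {
    one_recording(noise$seed)
  } else {
    lapply(seq_len(replicates), function(i) {
      one_recording(noise$seed + i - 1L)
    })
  }
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %d episodes (%s, %s), seed %d\n",
    length(x$traces), x$ground_truth$kind,
    if (x$subtracted) "P/8 subtracted" else "raw",
    x$ground_truth$noise$seed))
  invisible(x)
}

#' Q-V curve of a mixed homo/heterotetramer channel population
#'
#' Emulates a cell expressing both channel species: the population gating
#' current is the per-channel mixture
#' \eqn{(1-f)\,I_{homo}(t) + f\,I_{hetero}(t)} (each species contributing
#' its own per-channel charge), integrated and normalized into a Q-V curve.
#'
#' @param frac_hetero Fraction of heterotetrameric channels, in 0..1.
#' @param asm_homo,asm_hetero The two [channel_assembly()] objects.
#' @param prot A [voltage_protocol()].
#' @param pc A [physical_constants()] object.
#' @return A list with `qv` (the mixture [build_qv()] curve), `traces`
#'   (per-channel mixture currents, e0/ms) and `ground_truth`.
#' @export
mixed_population_qv <- function(frac_hetero, asm_homo, asm_hetero, prot,
                                pc = physical_constants()) {
  stopifnot(frac_hetero >= 0, frac_hetero <= 1)
  th <- simulate_protocol(asm_homo, prot, "gating", pc)
  te <- simulate_protocol(asm_hetero, prot, "gating", pc)
  mix <- lapply(seq_along(th), function(i) {
    tr <- th[[i]]
    tr$current <- (1 - frac_hetero) * th[[i]]$current +
      frac_hetero * te[[i]]$current
    tr$metadata$frac_hetero <- frac_hetero
    tr
  })
  list(qv = build_qv(mix), traces = mix,
       ground_truth = list(frac_hetero = frac_hetero,
                           asm_homo = asm_homo, asm_hetero = asm_hetero))
}
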