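#' Gating current from a state trajectory
#'
#' The gating (capacitive) current is the net rate of charge displacement:
#' summing over the activating direction of every edge,
#' \deqn{I_Q(t) = \sum_e z_e \left[ p_{from}(t)\,k_{fwd}(V(t)) -
#'       p_{to}(t)\,k_{rev}(V(t)) \right]}
#' in e0/ms per channel. Outward (activating) charge movement is positive.
#' Rates are evaluated at the per-sample command voltage, so the current
#' jumps at segment boundaries while the occupancies stay continuous.
#'
#' @param traj An [propagate_occupancy()] trajectory.
#' @param space The [build_state_space()] the trajectory was computed with
#'   (defaults to the one stored in the trajectory).
#' @param asm The generating [channel_assembly()]; required to evaluate the
#'   rate laws.
#' @param pc A [physical_constants()] object.
#' @param scale `"e0_per_ms"` (per-channel, default) or `"pA"` (population:
#'   multiplied by `asm$n_channels` and the elementary charge).
#' @return A `current_trace` of kind `"gating"`.
#' @export
gating_current_trace <- function(traj, space = traj$space, asm,
                                 pc = physical_constants(),
                                 scale = c("e0_per_ms", "pA")) {
  scale <- match.arg(scale)
  P <- traj$probabilities
  if (ncol(P) != nrow(space$states)) {
    stop("trajectory and state space dimensions do not match", call. = FALSE)
  }
  tr <- space$transitions
  iq <- numeric(nrow(P))
  for (vs in unique(traj$voltage)) {
    sel <- traj$voltage == vs
    r <- .edge_rates(asm, space, vs, pc)
    flux <- P[sel, tr$from, drop = FALSE] %*% diag(r$fwd * tr$charge) -
      P[sel, tr$to, drop = FALSE] %*% diag(r$rev * tr$charge)
    iq[sel] <- rowSums(flux)
  }
  units <- "e0/ms"
  if (scale == "pA") {
    iq <- iq * asm$n_channels * .E0_FC  # e0/ms -> fC/ms = pA
    units <- "pA"
  }
  current_trace(traj$time, iq, traj$episode_label, "gating", units,
                segments = traj$segments,
                metadata = list(scale = scale,
                                n_channels = asm$n_channels,
                                holding = traj$holding_potential))
}

#' Ionic current from a state trajectory
#'
#' Ohmic open-channel current
#' \eqn{I(t) = N g P_{open}(t) (V(t) - E_{rev})}, in pA when the
#' single-channel conductance is in nS and voltages in mV.
#'
#' @inheritParams gating_current_trace
#' @return A `current_trace` of kind `"ionic"` in pA.
#' @export
ionic_current_trace <- function(traj, asm, pc = physical_constants()) {
  P <- traj$probabilities
  space <- traj$space
  if (ncol(P) != nrow(space$states)) {
    stop("trajectory and assembly dimensions do not match", call. = FALSE)
  }
  p_open <- P[, space$states$open, drop = TRUE]
  i <- asm$n_channels * asm$single_channel_conductance * p_open *
    (traj$voltage - asm$reversal_potential)
  current_trace(traj$time, i, traj$episode_label, "ionic", "pA",
                segments = traj$segments,
                metadata = list(n_channels = asm$n_channels,
                                reversal = asm$reversal_potential,
                                holding = traj$holding_potential))
}

#' Simulate all episodes of a protocol
#'
#' Convenience wrapper: propagates every episode and converts to current
#' traces.
#'
#' @param asm A [channel_assembly()].
#' @param prot A [voltage_protocol()].
#' @param kind `"gating"` or `"ionic"`.
#' @param pc A [physical_constants()] object.
#' @param scale Passed to [gating_current_trace()].
#' @return A list of `current_trace` objects, one per episode.
#' @export
simulate_protocol <- function(asm, prot, kind = c("gating", "ionic"),
                              pc = physical_constants(),
                              scale = "e0_per_ms") {
  kind <- match.arg(kind)
  space <- build_state_space(asm)
  lapply(seq_len(n_episodes(prot)), function(i) {
    traj <- propagate_occupancy(asm, prot, i, pc, space)
    if (kind == "gating") {
      gating_current_trace(traj, space, asm, pc, scale = scale)
    } else {
      ionic_current_trace(traj, asm, pc)
    }
  })
}
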