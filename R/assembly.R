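#' Tetrameric channel assembly
#'
#' A channel is built from three identical "common" subunits (Kv2.1-like)
#' plus one fourth subunit that is either identical to them (homotetramer)
#' or carries distinct kinetics (a 3:1 heterotetramer with one electrically
#' silent subunit such as Kv6.4). Once all four voltage sensors are
#' activated the channel opens in a final concerted, voltage-independent and
#' charge-neutral step.
#'
#' @param common [subunit_kinetics()] of the three identical subunits.
#' @param distinct [subunit_kinetics()] of the fourth subunit; defaults to
#'   `common`, which expresses the homotetramer.
#' @param opening_rate Concerted opening rate, ms^-1 (voltage independent).
#' @param closing_rate Concerted closing rate, ms^-1 (voltage independent).
#'   The default pair (0.1, 1.0) keeps the open/closed equilibrium constant
#'   small (0.1) so the charge-neutral opening step adds little extra
#'   equilibrium weight to the fully-activated state and therefore barely
#'   distorts the Q-V curve relative to the voltage sensors' own Boltzmann
#'   equilibrium (see the methods vignette).
#' @param single_channel_conductance Open-channel conductance, nS.
#' @param reversal_potential Ionic reversal potential, mV.
#' @param n_channels Number of channels in the population (>= 1).
#'
#' @return An object of class `channel_assembly`.
#' @export
channel_assembly <- function(common, distinct = common,
                             opening_rate = 0.1, closing_rate = 1.0,
                             single_channel_conductance = 0.01,
                             reversal_potential = -80,
                             n_channels = 1) {
  stopifnot(inherits(common, "subunit_kinetics"),
            inherits(distinct, "subunit_kinetics"))
  if (!is.finite(opening_rate) || opening_rate <= 0 ||
      !is.finite(closing_rate) || closing_rate <= 0) {
    stop("`opening_rate` and `closing_rate` must be positive (ms^-1)",
         call. = FALSE)
  }
  if (!is.finite(n_channels) || n_channels < 1) {
    stop("`n_channels` must be >= 1", call. = FALSE)
  }
  structure(
    list(common = common, distinct = distinct,
         opening_rate = opening_rate, closing_rate = closing_rate,
         single_channel_conductance = single_channel_conductance,
         reversal_potential = reversal_potential,
         n_channels = n_channels),
    class = "channel_assembly"
  )
}

#' Is an assembly a homotetramer?
#'
#' Field-wise equality of the common and distinct subunit kinetics.
#' @param asm A [channel_assembly()].
#' @return Logical.
#' @export
is_homotetramer <- function(asm) {
  isTRUE(all.equal(unclass(asm$common), unclass(asm$distinct)))
}

#' @export
print.channel_assembly <- function(x, ...) {
  cat(sprintf("<channel_assembly> %s\n",
              if (is_homotetramer(x)) "homotetramer (4 identical subunits)"
              else "3:1 heterotetramer"))
  cat(sprintf("  opening %.3g ms^-1, closing %.3g ms^-1, g = %.3g nS, ",
              x$opening_rate, x$closing_rate, x$single_channel_conductance))
  cat(sprintf("Erev = %.0f mV, N = %g channels\n",
              x$reversal_potential, x$n_channels))
  invisible(x)
}

#' Reference gating parameters of Kv2.1-type channels
#'
#' Literature Boltzmann and kinetic parameters of ON-gating charge movement
#' used as package calibration defaults: the Kv2.1 homotetramer Q-V midpoint
#' -26.5 mV with slope 4.6 mV and a peak weighted decay time constant of
#' 16.5 ms (measured at -20 mV); for the 3:1 Kv2.1/Kv6.4 heterotetramer, a
#' hyperpolarized first Q-V component at -93.2 mV (slope 9.4 mV, tau 5.8 ms
#' at -70 mV) attributed to the silent Kv6.4 subunit, and a second component
#' at -21.8 mV (slope 5.8 mV, tau 14.5 ms at -20 mV) carried by the Kv2.1
#' subunits.
#'
#' @return A nested list of Boltzmann/tau parameter sets (`homo$common`,
#'   `hetero$distinct`, `hetero$common`), each with `Q_half`, `slope_k`
#'   (mV), `tau_ref` (ms) and `V_tau_ref` (mV).
#' @export
kv_reference_params <- function() {
  list(
    homo = list(
      common = list(Q_half = -26.5, slope_k = 4.6,
                    tau_ref = 16.5, V_tau_ref = -20)
    ),
    hetero = list(
      distinct = list(Q_half = -93.2, slope_k = 9.4,
                      tau_ref = 5.8, V_tau_ref = -70),
      common = list(Q_half = -21.8, slope_k = 5.8,
                    tau_ref = 14.5, V_tau_ref = -20)
    )
  )
}

.calibrate_set <- function(p, pc) {
  calibrate_from_boltzmann(p$Q_half, p$slope_k, p$tau_ref, p$V_tau_ref, pc)
}

#' Preset Kv2.1-like homotetramer assembly
#'
#' Common subunit calibrated to the reference homotetramer Q-V parameters
#' (see [kv_reference_params()]).
#'
#' @param pc A [physical_constants()] object.
#' @param ... Passed on to [channel_assembly()] (e.g. `n_channels`).
#' @return A homotetrameric [channel_assembly()].
#' @export
preset_homotetramer <- function(pc = physical_constants(), ...) {
  kin <- .calibrate_set(kv_reference_params()$homo$common, pc)
  channel_assembly(common = kin, distinct = kin, ...)
}

#' Preset 3:1 heterotetramer assembly with one silent subunit
#'
#' Common subunits calibrated to the reference heterotetramer second-component
#' parameters and the distinct (silent) subunit to the hyperpolarized first
#' component (see [kv_reference_params()]).
#'
#' @inheritParams preset_homotetramer
#' @return A heterotetrameric [channel_assembly()].
#' @export
preset_heterotetramer <- function(pc = physical_constants(), ...) {
  p <- kv_reference_params()$hetero
  channel_assembly(common = .calibrate_set(p$common, pc),
                   distinct = .calibrate_set(p$distinct, pc), ...)
}

#' Matched homotetramer control for an assembly
#'
#' Returns the same assembly with the distinct subunit replaced by a copy of
#' the common one. This is the proper control when isolating the effect of
#' the silent subunit: the simulated homotetramer is the same model with
#' identical common-subunit kinetics.
#'
#' @param asm A [channel_assembly()].
#' @return A homotetrameric [channel_assembly()] sharing `asm`'s common
#'   subunit and all other fields.
#' @export
matched_homotetramer <- function(asm) {
  asm$distinct <- asm$common
  asm
}
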