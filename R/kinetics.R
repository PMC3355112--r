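#' Voltage-sensor rate-law parameters for one subunit
#'
#' Each subunit's voltage sensor is modelled as a single closed-to-activated
#' transition with log-linear (exponential) voltage dependence of the
#' microscopic rates:
#' \deqn{\alpha(V) = \alpha_0 \exp(z_\alpha\delta_\alpha V / V_T), \quad
#'       \beta(V)  = \beta_0  \exp(-z_\beta\delta_\beta V / V_T)}
#' with \eqn{V_T = k_B T/e_0} the thermal voltage. The per-subunit
#' equilibrium activation is then a Boltzmann function with midpoint
#' \eqn{V_{1/2} = V_T \ln(\beta_0/\alpha_0)/(z_\alpha\delta_\alpha +
#' z_\beta\delta_\beta)} and slope factor
#' \eqn{k = V_T/(z_\alpha\delta_\alpha + z_\beta\delta_\beta)}.
#'
#' @param alpha0 Forward (activation) rate at 0 mV, ms^-1.
#' @param beta0 Backward (deactivation) rate at 0 mV, ms^-1.
#' @param z_alpha_delta Charge-distance product of the forward rate, e0 units.
#' @param z_beta_delta Charge-distance product of the backward rate, e0 units.
#'
#' @return An object of class `subunit_kinetics`.
#' @seealso [calibrate_from_boltzmann()] to construct one from measured
#'   Boltzmann parameters, [rate_alpha()], [rate_beta()], [subunit_vhalf()].
#' @export
subunit_kinetics <- function(alpha0, beta0, z_alpha_delta, z_beta_delta) {
  for (nm in c("alpha0", "beta0", "z_alpha_delta", "z_beta_delta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (alpha0 <= 0 || beta0 <= 0) {
    stop("`alpha0` and `beta0` must be positive (ms^-1)", call. = FALSE)
  }
  if (z_alpha_delta < 0 || z_beta_delta < 0 ||
      z_alpha_delta + z_beta_delta <= 0) {
    stop("charge-distance products must be >= 0 with a positive sum",
         call. = FALSE)
  }
  structure(
    list(alpha0 = alpha0, beta0 = beta0,
         z_alpha_delta = z_alpha_delta, z_beta_delta = z_beta_delta),
    class = "subunit_kinetics"
  )
}

#' @export
print.subunit_kinetics <- function(x, ...) {
  pc <- physical_constants()
  cat(sprintf(
    paste0("<subunit_kinetics> alpha0 = %.4g, beta0 = %.4g ms^-1; ",
           "z_a*d_a = %.3f, z_b*d_b = %.3f e0\n",
           "  equilibrium midpoint %.1f mV, slope %.2f mV (at 298.15 K)\n"),
    x$alpha0, x$beta0, x$z_alpha_delta, x$z_beta_delta,
    subunit_vhalf(x, pc),
    pc$thermal_voltage / (x$z_alpha_delta + x$z_beta_delta)))
  invisible(x)
}

.check_voltage <- function(V) {
  if (!is.numeric(V) || length(V) < 1L || any(!is.finite(V))) {
    stop("voltage must be finite and numeric (mV)", call. = FALSE)
  }
  V
}

#' Forward (activation) rate of a voltage sensor
#'
#' @param kin A [subunit_kinetics()] object.
#' @param V Membrane voltage, mV (vectorized).
#' @param pc A [physical_constants()] object.
#' @return Rate in ms^-1; strictly increasing in `V`.
#' @export
rate_alpha <- function(kin, V, pc = physical_constants()) {
  .check_voltage(V)
  kin$alpha0 * exp(kin$z_alpha_delta * V / pc$thermal_voltage)
}

#' Backward (deactivation) rate of a voltage sensor
#'
#' @inheritParams rate_alpha
#' @return Rate in ms^-1; strictly decreasing in `V`.
#' @export
rate_beta <- function(kin, V, pc = physical_constants()) {
  .check_voltage(V)
  kin$beta0 * exp(-kin$z_beta_delta * V / pc$thermal_voltage)
}

#' Equilibrium midpoint voltage of one subunit
#'
#' The voltage at which \eqn{\alpha(V) = \beta(V)}, i.e. the midpoint of the
#' subunit's equilibrium Boltzmann activation curve.
#'
#' @inheritParams rate_alpha
#' @return Midpoint in mV.
#' @export
subunit_vhalf <- function(kin, pc = physical_constants()) {
  pc$thermal_voltage * log(kin$beta0 / kin$alpha0) /
    (kin$z_alpha_delta + kin$z_beta_delta)
}

#' Total per-subunit gating charge
#'
#' Sum of the forward and backward charge-distance products: the charge that
#' one voltage sensor moves in its closed-to-activated step.
#'
#' @inheritParams rate_alpha
#' @return Charge in e0 units.
#' @export
subunit_charge <- function(kin) {
  kin$z_alpha_delta + kin$z_beta_delta
}

#' Equilibrium activation probability of one subunit
#'
#' @inheritParams rate_alpha
#' @return \eqn{\alpha/(\alpha+\beta)}, a Boltzmann function of `V`.
#' @export
subunit_open_fraction <- function(kin, V, pc = physical_constants()) {
  a <- rate_alpha(kin, V, pc)
  b <- rate_beta(kin, V, pc)
  a / (a + b)
}

#' Calibrate subunit rate laws from measured Boltzmann and decay parameters
#'
#' Published gating data are typically reported as the Boltzmann midpoint and
#' slope of the charge-voltage curve plus a decay time constant at some
#' voltage, not as microscopic rate constants. This routine inverts that
#' parameterization: the total per-subunit charge is taken from the slope via
#' \eqn{z = k_B T/(\mathrm{slope}\cdot e_0)} and split symmetrically between
#' the forward and backward rates (which places the maximum of the
#' \eqn{\tau = 1/(\alpha+\beta)} bell exactly at the midpoint), the ratio
#' \eqn{\beta_0/\alpha_0} is set so the equilibrium midpoint equals `Q_half`,
#' and the overall rate scale is set so that
#' \eqn{1/(\alpha(V_{ref}) + \beta(V_{ref})) = \tau_{ref}}.
#'
#' @param Q_half Boltzmann midpoint of the target charge-voltage curve, mV.
#' @param slope_k Boltzmann slope factor, mV (> 0).
#' @param tau_ref Relaxation time constant at `V_tau_ref`, ms (> 0).
#' @param V_tau_ref Voltage at which `tau_ref` was measured, mV. Defaults to
#'   `Q_half` (the bell maximum under the symmetric split).
#' @param pc A [physical_constants()] object.
#'
#' @return A [subunit_kinetics()] object whose equilibrium activation curve
#'   is a Boltzmann with midpoint `Q_half` and slope `slope_k`.
#' @export
calibrate_from_boltzmann <- function(Q_half, slope_k, tau_ref,
                                     V_tau_ref = Q_half,
                                     pc = physical_constants()) {
  if (!is.finite(Q_half) || !is.finite(slope_k) || !is.finite(tau_ref) ||
      !is.finite(V_tau_ref)) {
    stop("calibration inputs must be finite", call. = FALSE)
  }
  if (slope_k <= 0) stop("`slope_k` must be > 0 (mV)", call. = FALSE)
  if (tau_ref <= 0) stop("`tau_ref` must be > 0 (ms)", call. = FALSE)
  vt <- pc$thermal_voltage
  z <- vt / slope_k          # total per-subunit charge, e0
  za <- z / 2                # symmetric split
  zb <- z / 2
  # alpha0 = 1 reference, beta0/alpha0 pins the midpoint, then rescale both
  # so that 1/(alpha + beta) = tau_ref at V_tau_ref.
  log_ratio <- z * Q_half / vt        # log(beta0/alpha0)
  a_ref <- exp(za * V_tau_ref / vt)
  b_ref <- exp(log_ratio - zb * V_tau_ref / vt)
  scale <- 1 / (tau_ref * (a_ref + b_ref))
  if (!is.finite(scale) || scale <= 0) {
    stop("calibration failed: inconsistent constraints", call. = FALSE)
  }
  subunit_kinetics(alpha0 = scale,
                   beta0 = scale * exp(log_ratio),
                   z_alpha_delta = za, z_beta_delta = zb)
}
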