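#' Physical constants for gating calculations
#'
#' Bundles the absolute temperature with the derived thermal voltage
#' \eqn{k_B T / e_0}, the natural voltage scale of voltage-sensor movement.
#' All rate laws and charge-from-slope conversions in the package take a
#' `physical_constants` object so the temperature is set in exactly one place.
#'
#' @param temperature Absolute temperature in kelvin. Default 298.15 K
#'   (25 °C), giving a thermal voltage of about 25.693 mV.
#'
#' @return An object of class `physical_constants` with fields
#'   `temperature` (K) and `thermal_voltage` (mV).
#' @examples
#' pc <- physical_constants()
#' pc$thermal_voltage  # ~25.693 mV
#' @export
physical_constants <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive finite number (kelvin)",
         call. = FALSE)
  }
  k_B <- 1.380649e-23   # J/K
  e0 <- 1.602176634e-19 # C
  structure(
    list(
      temperature = temperature,
      thermal_voltage = 1000 * k_B * temperature / e0 # mV
    ),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat(sprintf("<physical_constants> T = %.2f K, kT/e0 = %.4f mV\n",
              x$temperature, x$thermal_voltage))
  invisible(x)
}

# elementary charge in fC (1 e0 = 1.602e-4 fC); used for pA conversions
.E0_FC <- 1.602176634e-4
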