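#' Skin maximum permissible exposure fluence
#'
#' Nanosecond-pulse skin MPE for wavelengths in the 700 to 1050 nm band:
#' `MPE = 2.0 * C_A * 1e-2 J/cm^2` with the wavelength correction factor
#' `C_A = 10^(2 (lambda - 0.700))` (lambda in micrometers). Returned in
#' mJ/cm^2, unrounded. Other wavelength bands and exposure durations are
#' not implemented and are rejected.
#'
#' @param wavelength_nm Laser wavelength in nm, within `[700, 1050]`.
#' @return MPE fluence in mJ/cm^2.
#' @examples
#' mpe_skin_fluence(700)  # 20 mJ/cm^2 (C_A = 1)
#' mpe_skin_fluence(900)  # ~50.24 mJ/cm^2
#' @export
mpe_skin_fluence <- function(wavelength_nm) {
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1L)
  if (wavelength_nm < 700 || wavelength_nm > 1050) {
    stop("only the 700-1050 nm nanosecond-pulse skin MPE band is supported")
  }
  lambda_um <- wavelength_nm / 1000
  ca <- 10^(2 * (lambda_um - 0.700))
  20 * ca  # 2.0 * C_A * 1e-2 J/cm^2, expressed in mJ/cm^2
}

#' Maximum per-pulse energy at a fiber tip
#'
#' Converts an MPE fluence into the maximum per-pulse energy deliverable
#' through an optical fiber, assuming a flat-top beam over the fiber core:
#' `E = fluence * pi * (diameter/2)^2` with the area in cm^2 and the result
#' in microjoules.
#'
#' @param fluence MPE fluence in mJ/cm^2 (>= 0).
#' @param diameter_mm Fiber core diameter in mm (> 0).
#' @return Maximum pulse energy in microjoules.
#' @examples
#' max_pulse_energy(mpe_skin_fluence(900), 1.0)  # ~394.6 uJ
#' @export
max_pulse_energy <- function(fluence, diameter_mm) {
  stopifnot(fluence >= 0, diameter_mm > 0)
  area_cm2 <- pi * (diameter_mm / 20)^2  # mm -> cm radius
  fluence * area_cm2 * 1000              # mJ -> uJ
}

#' Laser-safety energy limit summary
#'
#' @param wavelength_nm Laser wavelength in nm.
#' @param diameter_mm Fiber core diameter in mm.
#' @return An object of class `pa_energy_limit`: list with
#'   `wavelength_nm`, `mpe_mj_cm2`, `fiber_diameter_mm`,
#'   `max_energy_uj`.
#' @examples
#' energy_limit(900, 1.0)
#' @export
energy_limit <- function(wavelength_nm, diameter_mm) {
  fl <- mpe_skin_fluence(wavelength_nm)
  structure(
    list(wavelength_nm = wavelength_nm,
         mpe_mj_cm2 = fl,
         fiber_diameter_mm = diameter_mm,
         max_energy_uj = max_pulse_energy(fl, diameter_mm)),
    class = "pa_energy_limit")
}

#' @export
print.pa_energy_limit <- function(x, ...) {
  cat(sprintf("<pa_energy_limit> %g nm: MPE %.4g mJ/cm^2; %g-mm fiber core -> %.4g uJ/pulse\n",
              x$wavelength_nm, x$mpe_mj_cm2, x$fiber_diameter_mm,
              x$max_energy_uj))
  invisible(x)
}
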