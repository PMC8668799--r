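#' Vapor pressure from specific humidity
#'
#' Bolton's relation between specific humidity q (kg kg-1) and vapor
#' pressure (hPa) at air pressure P (hPa):
#' `e = q * P / (0.378 * q + 0.622)`.
#'
#' @param q specific humidity (kg kg-1), non-negative
#' @param P air pressure (hPa), positive
#' @return vapor pressure e (hPa)
#' @export
vapor_pressure <- function(q, P) {
  if (any(q < 0, na.rm = TRUE)) stopf("vapor_pressure: negative specific humidity")
  if (any(P <= 0, na.rm = TRUE)) stopf("vapor_pressure: non-positive pressure")
  q * P / (0.378 * q + 0.622)
}

#' Saturation vapor pressure over water
#'
#' Magnus-type formula
#' `E = 6.122 * exp(17.62 * ta / (243.12 + ta))` with `ta` in degC and `E`
#' in hPa.  At 0 degC the exponent vanishes and `E = 6.122` hPa exactly.
#'
#' @param ta air temperature (degC), greater than -243.12
#' @return saturation vapor pressure E (hPa)
#' @export
saturation_vapor_pressure <- function(ta) {
  if (any(ta <= -243.12, na.rm = TRUE))
    stopf("saturation_vapor_pressure: temperature at or below -243.12 degC")
  6.122 * exp(17.62 * ta / (243.12 + ta))
}

#' Relative humidity from specific humidity
#'
#' `rh = e / E * 100` with the vapor pressures of
#' [vapor_pressure()] and [saturation_vapor_pressure()].  Values outside
#' \[0, 100\] (possible for supersaturated model output) are clipped; the
#' number of clipped values is attached as attribute `n_clipped`.
#'
#' @param q specific humidity (kg kg-1)
#' @param P air pressure (hPa)
#' @param ta air temperature (degC)
#' @return relative humidity (%), clipped to \[0, 100\]
#' @export
specific_humidity_to_rh <- function(q, P, ta) {
  rh <- vapor_pressure(q, P) / saturation_vapor_pressure(ta) * 100
  clipped <- sum(rh < 0 | rh > 100, na.rm = TRUE)
  rh <- clamp(rh, 0, 100)
  attr(rh, "n_clipped") <- clipped
  rh
}
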