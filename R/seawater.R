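#' Seawater density at one atmosphere
#'
#' Density of seawater at surface pressure from the one-atmosphere
#' International Equation of State of Seawater (Millero & Poisson 1981,
#' EOS-80), evaluated at practical salinity and in situ temperature.
#' Closed-chamber incubations at a few metres depth are treated as
#' surface-pressure water; the pressure terms of the full equation of state
#' are deliberately omitted.
#'
#' Over the tropical range (20--35 degC, S 30--40) the returned density
#' increases monotonically with salinity and decreases with temperature.
#'
#' @param salinity Practical salinity (dimensionless, PSS-78). Must lie in
#'   `[0, 45]`.
#' @param temperature Water temperature (degC, ITS-68 as used by the fit).
#'   Must lie in `[-2, 40]`.
#' @return Density in kg L^-1 (numeric, vectorised over the inputs).
#' @examples
#' sw_density(35, 28)       # warm reef water, ~1.0224 kg L^-1
#' sw_density(0, 3.98)      # pure-water density maximum, ~1.0000
#' @seealso [o2_saturation()] for the matching solubility fit.
#' @export
sw_density <- function(salinity, temperature) {
  check_sal_temp(salinity, temperature)
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  (rho_w + a * s + b * s^1.5 + c0 * s^2) / 1000
}

#' Equilibrium oxygen solubility of seawater
#'
#' Air-saturated dissolved-oxygen concentration from the Garcia & Gordon
#' (1992) combined fit (Benson & Krause coefficients), converted from
#' umol kg^-1 to umol L^-1 with [sw_density()]. This anchors the
#' supersaturation and hypoxia thresholds used by the chamber-volume safety
#' classifier: a light incubation that drives O2 far above this value, or a
#' dark incubation that drives it towards zero, is flagged as unsafe.
#'
#' @inheritParams sw_density
#' @return Saturation concentration in umol L^-1, decreasing in both
#'   temperature and salinity.
#' @examples
#' o2_saturation(35, 28)    # ~201 umol L^-1 on a warm reef
#' @export
o2_saturation <- function(salinity, temperature) {
  check_sal_temp(salinity, temperature)
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  ln_c <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    -2.75915e-7 * salinity^2
  exp(ln_c) * sw_density(salinity, temperature)  # umol/kg * kg/L
}

#' Oxygen saturation state as a percentage
#'
#' @param o2 Dissolved oxygen concentration (umol L^-1), `>= 0`.
#' @inheritParams sw_density
#' @return `100 * o2 / o2_saturation(salinity, temperature)` (%).
#' @examples
#' saturation_percent(o2_saturation(35, 28), 35, 28)  # exactly 100
#' @export
saturation_percent <- function(o2, salinity, temperature) {
  if (any(o2 < 0, na.rm = TRUE)) {
    stop("`o2` must be non-negative (umol L^-1)", call. = FALSE)
  }
  100 * o2 / o2_saturation(salinity, temperature)
}

# shared range validation; errors name the offending field
check_sal_temp <- function(salinity, temperature) {
  if (!is.numeric(salinity) || any(!is.finite(salinity)) ||
      any(salinity < 0 | salinity > 45)) {
    stop("`salinity` must be finite and within [0, 45]", call. = FALSE)
  }
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature < -2 | temperature > 40)) {
    stop("`temperature` must be finite and within [-2, 40] degC",
         call. = FALSE)
  }
  invisible(TRUE)
}
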