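#' Saturation water-vapour pressure
#'
#' Arden Buck formulation over liquid water, returned in torr. Valid over
#' the 0-30 C range used for temperate seawater work.
#'
#' @param temperature water temperature (degrees C).
#' @return vapour pressure in torr.
#' @export
water_vapor_pressure <- function(temperature) {
  kpa <- 0.61121 * exp((18.678 - temperature / 234.5) *
                         (temperature / (257.14 + temperature)))
  kpa * 7.50062
}

#' Convert percent air saturation to oxygen partial pressure
#'
#' Optode readings in percent air saturation are converted to torr, with the
#' atmospheric O2 mole fraction fixed at 0.2094 and the barometric pressure
#' corrected for saturation water-vapour pressure at the measurement
#' temperature.
#'
#' @param percent oxygen saturation in percent of air saturation (>= 0).
#' @param barometric barometric pressure in torr. Defaults to 760 torr with
#'   a warning, for records lacking pressure metadata.
#' @param temperature water temperature (degrees C).
#' @return partial pressure in torr.
#' @examples
#' percent_airsat_to_torr(100, 760, 12)
#' @export
percent_airsat_to_torr <- function(percent, barometric = NULL,
                                   temperature = 12) {
  if (any(percent < 0, na.rm = TRUE))
    stop_validation("percent air saturation must be >= 0")
  if (is.null(barometric)) {
    warning("barometric pressure missing; assuming 760 torr")
    barometric <- 760
  }
  pv <- water_vapor_pressure(temperature)
  if (any(barometric <= pv))
    stop_validation("barometric pressure must exceed water vapour pressure")
  (percent / 100) * 0.2094 * (barometric - pv)
}

#' Oxygen solubility of seawater
#'
#' Solubility coefficient alpha_O2 in uM torr^-1, from the Benson-Krause
#' oxygen solubility data as refit by Garcia and Gordon (umol kg^-1 at air
#' saturation), converted to a per-litre, per-torr coefficient with the
#' one-atmosphere seawater density equation of state and the water-vapour
#' corrected O2 partial pressure of air-saturated water.
#'
#' @param temperature water temperature, 0-30 C.
#' @param salinity practical salinity, 0-40.
#' @return alpha_O2 in uM torr^-1 (= nmol ml^-1 torr^-1).
#' @examples
#' oxygen_solubility(12, 33) # ~1.8 uM/torr
#' @export
oxygen_solubility <- function(temperature, salinity) {
  if (any(temperature < 0 | temperature > 30))
    stop_validation("temperature must be within 0-30 C")
  if (any(salinity < 0 | salinity > 40))
    stop_validation("salinity must be within 0-40")
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  c_sat <- exp(lnc) # umol/kg at 100% air saturation
  po2_sat <- 0.2094 * (760 - water_vapor_pressure(temperature))
  c_sat * seawater_density(temperature, salinity) / 1000 / po2_sat
}

#' One-atmosphere seawater density
#'
#' International one-atmosphere equation of state of seawater
#' (Millero-Poisson form), kg m^-3.
#'
#' @param temperature degrees C.
#' @param salinity practical salinity.
#' @return density in kg m^-3.
#' @export
seawater_density <- function(temperature, salinity) {
  t <- temperature
  s <- salinity
  rw <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  rw + a * s + b * s^1.5 + 4.8314e-4 * s^2
}

#' Advance a delayed outflow series to the cardiovascular clock
#'
#' The outlet optode lags the animal by the chamber mixing time, so a value
#' recorded at time t reflects consumption at t - delay. Advancing the
#' series by `delay` (an integer-sample left shift) synchronises computed
#' metabolic rates with instantaneous cardiovascular recordings. Samples at
#' the end of the record without support are set to `NA`, never
#' extrapolated.
#'
#' @param x numeric series sampled at `dt_min` minute intervals.
#' @param delay delay in minutes, 0-10.
#' @param dt_min sampling interval in minutes.
#' @return the shifted series, same length as `x`.
#' @examples
#' align_delay(1:6, delay = 3) # 4 5 6 NA NA NA
#' @export
align_delay <- function(x, delay, dt_min = 1) {
  assert_scalar_num(delay, "delay", lower = 0, upper = 10)
  shift <- as.integer(round(delay / dt_min))
  n <- length(x)
  if (shift >= n)
    stop_validation("delay (", delay, " min) exceeds the record length")
  if (shift == 0) return(x)
  c(x[(shift + 1):n], rep(NA_real_, shift))
}

#' Compute whole-animal oxygen consumption from paired optode traces
#'
#' Flow-through respirometry metabolic rate from the inlet-outlet oxygen
#' partial-pressure difference:
#' `mo2 = delta_P * alpha_O2 * FR / w_f` in nmol O2 min^-1 g^-1, where
#' `alpha_O2` is the oxygen solubility (uM torr^-1 = nmol ml^-1 torr^-1),
#' `FR` the water flow rate (ml min^-1) and `w_f` the animal fresh weight
#' (g). The outflow series is first advanced by `delay` minutes
#' (see [align_delay()]) so the result is synchronous with cardiovascular
#' recordings. Negative transients caused by sensor noise are retained and
#' flagged, not clipped, so downstream range statistics see the full
#' distribution.
#'
#' @param pair an `optode_pair` data frame with columns `time_min`,
#'   `inflow_torr`, `outflow_torr` (see [make_optode_traces()] or
#'   [read_optode_csv()]).
#' @param flow_rate water flow through the chamber, ml min^-1 (> 0).
#' @param mass animal fresh weight in g (> 0).
#' @param delay inlet-outlet signal delay in minutes (default 0, i.e. no
#'   shift).
#' @param deconvolve if `TRUE`, invert the first-order chamber-mixing kernel
#'   (time constant `delay`) instead of applying an integer-sample shift.
#'   The shift corrects timing only; deconvolution additionally restores
#'   fast transients smeared by chamber mixing and is exact for a
#'   single-compartment chamber. Default `FALSE`.
#' @param alpha oxygen solubility in uM torr^-1; computed from the pair's
#'   `temperature`/`salinity` attributes when `NULL`.
#' @return A data frame of class `metabolic_trace` with columns `time`
#'   (min), `mo2` (nmol min^-1 g^-1), `delta_p` (torr) and `flag`
#'   (`"negative"` for noise-driven negative transients, `NA` otherwise).
#' @export
compute_mo2 <- function(pair, flow_rate, mass, delay = 0, deconvolve = FALSE,
                        alpha = NULL) {
  assert_scalar_num(flow_rate, "flow_rate")
  if (flow_rate <= 0) stop_config("`flow_rate` must be > 0")
  assert_scalar_num(mass, "mass")
  if (mass <= 0) stop_validation("`mass` must be > 0")
  need <- c("time_min", "inflow_torr", "outflow_torr")
  if (!all(need %in% names(pair)))
    stop_validation("`pair` must have columns ", paste(need, collapse = ", "))
  if (length(pair$inflow_torr) != length(pair$outflow_torr))
    stop_validation("inflow and outflow traces differ in length")
  if (is.null(alpha)) {
    temp <- attr(pair, "temperature")
    sal <- attr(pair, "salinity")
    if (is.null(temp) || is.null(sal))
      stop_validation("`alpha` not given and pair lacks temperature/salinity ",
                      "attributes")
    alpha <- oxygen_solubility(temp, sal)
  }
  dt <- if (nrow(pair) > 1) diff(pair$time_min[1:2]) else 1
  if (deconvolve) {
    deficit <- pair$inflow_torr - pair$outflow_torr
    delta_p <- first_order_unmix(deficit, tau = delay, dt = dt)
  } else {
    outflow <- align_delay(pair$outflow_torr, delay, dt_min = dt)
    delta_p <- pair$inflow_torr - outflow
  }
  mo2 <- delta_p * alpha * flow_rate / mass
  out <- data.frame(
    time = pair$time_min,
    mo2 = mo2,
    delta_p = delta_p,
    flag = ifelse(!is.na(mo2) & mo2 < 0, "negative", NA_character_),
    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "flow_rate") <- flow_rate
  attr(out, "mass") <- mass
  attr(out, "delay") <- delay
  class(out) <- c("metabolic_trace", "data.frame")
  out
}

#' @export
print.metabolic_trace <- function(x, ...) {
  ok <- !is.na(x$mo2)
  cat(sprintf(
    "Metabolic trace: %d samples, MO2 median %.2f (IQR %.2f-%.2f) nmol min^-1 g^-1\n",
    nrow(x), stats::median(x$mo2[ok]),
    stats::quantile(x$mo2[ok], 0.25), stats::quantile(x$mo2[ok], 0.75)))
  cat(sprintf("  alpha = %.3f uM/torr, FR = %g ml/min, mass = %g g, delay = %g min\n",
              attr(x, "alpha"), attr(x, "flow_rate"), attr(x, "mass"),
              attr(x, "delay")))
  invisible(x)
}
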