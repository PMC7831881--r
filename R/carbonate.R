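#' Equilibrium constants of the seawater CO2 system
#'
#' Returns the dissociation and solubility constants used by the carbonate
#' solver: K0 (CO2 solubility, Weiss), K1 and K2 (carbonic acid, Mehrbach
#' data as refit by Dickson and Millero, seawater pH scale), KB (boric
#' acid, Dickson), KW (water, Millero), KS (bisulfate, Dickson, free
#' scale), the total sulfate ST (Morris and Riley) and total boron BT
#' (Uppstroem boron-to-chlorinity ratio). Constants carrying a pH scale can
#' be returned on the seawater or free scale; conversion uses the sulfate
#' correction factor `1 + ST/KS` (fluoride omitted, the sulfate term being
#' the dominant correction).
#'
#' @param temperature water temperature in degrees C (0-35).
#' @param salinity practical salinity (19-43, validity of the Mehrbach
#'   refit).
#' @param scale pH scale of the returned K1, K2, KB, KW: `"sws"` (default)
#'   or `"free"`.
#' @return list with elements `k0` (mol kg^-1 atm^-1), `k1`, `k2`, `kb`,
#'   `kw`, `ks`, `st`, `bt` (mol kg^-1) and `scale`.
#' @export
equilibrium_constants <- function(temperature, salinity,
                                  scale = c("sws", "free")) {
  scale <- match.arg(scale)
  if (temperature < 0 || temperature > 35)
    stop_validation("temperature outside the 0-35 C validity range")
  if (salinity < 19 || salinity > 43)
    stop_validation("salinity outside the 19-43 validity range")
  tk <- temperature + 273.15
  s <- salinity

  # CO2 solubility, mol kg^-1 atm^-1
  lnk0 <- -60.2409 + 93.4517 * (100 / tk) + 23.3585 * log(tk / 100) +
    s * (0.023517 - 0.023656 * (tk / 100) + 0.0047036 * (tk / 100)^2)
  k0 <- exp(lnk0)

  # carbonic acid, Mehrbach data refit (SWS scale)
  pk1 <- 3670.7 / tk - 62.008 + 9.7944 * log(tk) - 0.0118 * s +
    0.000116 * s^2
  pk2 <- 1394.7 / tk + 4.777 - 0.0184 * s + 0.000118 * s^2
  k1 <- 10^-pk1
  k2 <- 10^-pk2

  # boric acid (total scale fit; the total-to-SWS difference is the
  # fluoride term, omitted here)
  sq <- sqrt(s)
  lnkb <- (-8966.90 - 2890.53 * sq - 77.942 * s + 1.728 * s * sq -
             0.0996 * s^2) / tk +
    148.0248 + 137.1942 * sq + 1.62142 * s -
    (24.4344 + 25.085 * sq + 0.2474 * s) * log(tk) + 0.053105 * sq * tk
  kb <- exp(lnkb)

  # water self-ionisation (SWS scale)
  lnkw <- 148.9802 - 13847.26 / tk - 23.6521 * log(tk) +
    (-5.977 + 118.67 / tk + 1.0495 * log(tk)) * sq - 0.01615 * s
  kw <- exp(lnkw)

  # bisulfate, free scale, converted from mol/kg-H2O to mol/kg-solution
  ion <- 19.924 * s / (1000 - 1.005 * s)
  sqi <- sqrt(ion)
  lnks <- -4276.1 / tk + 141.328 - 23.093 * log(tk) +
    (-13856 / tk + 324.57 - 47.986 * log(tk)) * sqi +
    (35474 / tk - 771.54 + 114.723 * log(tk)) * ion -
    2698 / tk * ion * sqi + 1776 / tk * ion^2
  ks <- exp(lnks) * (1 - 0.001005 * s)

  st <- 0.02824 * s / 35
  bt <- 0.000416 * s / 35

  if (scale == "free") {
    f <- 1 + st / ks
    k1 <- k1 / f
    k2 <- k2 / f
    kb <- kb / f
    kw <- kw / f
  }
  list(k0 = k0, k1 = k1, k2 = k2, kb = kb, kw = kw, ks = ks,
       st = st, bt = bt, scale = scale)
}

#' Convert pH between seawater scales
#'
#' `[H+]_sws = [H+]_free * (1 + ST/KS)` (sulfate correction only; fluoride
#' omitted).
#'
#' @param ph pH value.
#' @param from,to `"free"` or `"sws"`.
#' @param temperature,salinity water conditions.
#' @return converted pH.
#' @export
ph_convert <- function(ph, from, to, temperature, salinity) {
  from <- match.arg(from, c("free", "sws"))
  to <- match.arg(to, c("free", "sws"))
  if (from == to) return(ph)
  k <- equilibrium_constants(temperature, salinity)
  off <- log10(1 + k$st / k$ks)
  if (from == "free") ph - off else ph + off
}

#' Convert NIST-buffer pH to the free seawater scale
#'
#' Electrodes calibrated in dilute NIST buffers over-read the hydrogen-ion
#' activity in seawater; the conversion applies an ionic-strength
#' correction for the single-ion activity coefficient of H+ (Davies
#' equation at the ionic strength of the sample). The map is strictly
#' monotone and exactly invertible via [ph_free_to_nist()].
#'
#' @param ph_nist pH on the NIST (activity) scale, 6-9.
#' @param temperature,salinity water conditions.
#' @return pH on the free seawater scale.
#' @export
ph_nist_to_free <- function(ph_nist, temperature, salinity) {
  if (any(ph_nist < 6 | ph_nist > 9))
    stop_validation("pH_NIST outside the supported 6-9 range")
  ph_nist + .log_gamma_h(salinity)
}

#' @rdname ph_nist_to_free
#' @param ph_free pH on the free seawater scale.
#' @export
ph_free_to_nist <- function(ph_free, temperature, salinity) {
  ph_free - .log_gamma_h(salinity)
}

# log10 activity coefficient of H+ from the Davies equation at the
# seawater ionic strength; the resulting NIST-to-free offset is ~ -0.1 and
# bounded well below 0.2 units over oceanic salinities.
#' @keywords internal
.log_gamma_h <- function(salinity) {
  ion <- 19.924 * salinity / (1000 - 1.005 * salinity)
  a <- 0.509
  -a * (sqrt(ion) / (1 + sqrt(ion)) - 0.3 * ion)
}

#' Solve the seawater CO2 system from the (pCO2, pH) pair
#'
#' Computes dissolved CO2, bicarbonate, carbonate, DIC and total
#' alkalinity from measured pCO2 and pH:
#' `CO2* = K0 pCO2`, `HCO3- = CO2* K1 / [H+]`, `CO3^2- = HCO3- K2 / [H+]`,
#' `DIC = CO2* + HCO3- + CO3^2-`,
#' `TA = HCO3- + 2 CO3^2- + B(OH)4- + OH- - H+` (phosphate and silicate
#' taken as zero). Constants and the hydrogen-ion concentration are kept on
#' one consistent scale internally; the returned concentrations are
#' scale-free.
#'
#' `ph_scale` declares the scale of the supplied pH. The default `"sws"`
#' pairs the pH value directly with the seawater-scale constants; pass
#' `"free"` to apply the sulfate scale conversion first.
#'
#' @param pco2 water CO2 partial pressure in uatm (> 0).
#' @param ph water pH.
#' @param temperature degrees C.
#' @param salinity practical salinity.
#' @param ph_scale scale of `ph`: `"sws"` (default) or `"free"`.
#' @return Object of class `seawater_state`: a list with `temperature`,
#'   `salinity`, `pco2`, `ph`, `ph_scale`, and `co2_star`, `hco3`, `co3`,
#'   `dic`, `ta` in mmol kg^-1.
#' @examples
#' solve_carbonate(478, 8.06, 11.85, 32.75)
#' @export
solve_carbonate <- function(pco2, ph, temperature, salinity,
                            ph_scale = c("sws", "free")) {
  ph_scale <- match.arg(ph_scale)
  assert_scalar_num(pco2, "pco2")
  if (pco2 <= 0) stop_validation("`pco2` must be > 0")
  k <- equilibrium_constants(temperature, salinity, scale = "sws")
  h <- 10^-ph
  if (ph_scale == "free") h <- h * (1 + k$st / k$ks)

  co2 <- k$k0 * pco2 * 1e-6
  hco3 <- co2 * k$k1 / h
  co3 <- hco3 * k$k2 / h
  dic <- co2 + hco3 + co3
  boh4 <- k$bt * k$kb / (k$kb + h)
  oh <- k$kw / h
  ta <- hco3 + 2 * co3 + boh4 + oh - h

  structure(list(temperature = temperature, salinity = salinity,
                 pco2 = pco2, ph = ph, ph_scale = ph_scale,
                 co2_star = co2 * 1e3, hco3 = hco3 * 1e3, co3 = co3 * 1e3,
                 dic = dic * 1e3, ta = ta * 1e3),
            class = "seawater_state")
}

#' Re-solve the CO2 system from total alkalinity and DIC
#'
#' Inverts the system for internal-consistency checks: given (TA, DIC) the
#' hydrogen-ion concentration is found by root bisection of the alkalinity
#' balance, then pCO2 and pH are recovered.
#'
#' @param ta total alkalinity in mmol kg^-1.
#' @param dic dissolved inorganic carbon in mmol kg^-1.
#' @param temperature,salinity water conditions.
#' @return Object of class `seawater_state` (pH on the seawater scale).
#' @export
carbonate_from_ta_dic <- function(ta, dic, temperature, salinity) {
  k <- equilibrium_constants(temperature, salinity, scale = "sws")
  ta <- ta * 1e-3
  dic <- dic * 1e-3
  resid <- function(ph) {
    h <- 10^-ph
    denom <- h^2 + k$k1 * h + k$k1 * k$k2
    hco3 <- dic * k$k1 * h / denom
    co3 <- dic * k$k1 * k$k2 / denom
    boh4 <- k$bt * k$kb / (k$kb + h)
    hco3 + 2 * co3 + boh4 + k$kw / h - h - ta
  }
  ph <- stats::uniroot(resid, c(4, 10), tol = 1e-12)$root
  h <- 10^-ph
  denom <- h^2 + k$k1 * h + k$k1 * k$k2
  co2 <- dic * h^2 / denom
  solve_carbonate(pco2 = co2 / k$k0 * 1e6, ph = ph,
                  temperature = temperature, salinity = salinity,
                  ph_scale = "sws")
}

#' @export
print.seawater_state <- function(x, ...) {
  cat(sprintf("Seawater CO2 system at %.2f C, S = %.2f\n",
              x$temperature, x$salinity))
  cat(sprintf("  input: pCO2 = %.0f uatm, pH = %.3f (%s scale)\n",
              x$pco2, x$ph, x$ph_scale))
  cat(sprintf("  CO2* = %.4f, HCO3- = %.3f, CO3^2- = %.4f mmol/kg\n",
              x$co2_star, x$hco3, x$co3))
  cat(sprintf("  DIC = %.3f, TA = %.3f mmol/kg\n", x$dic, x$ta))
  invisible(x)
}
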