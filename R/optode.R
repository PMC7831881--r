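#' Specification of a flow-through respirometry chamber
#'
#' @param volume_l chamber volume in litres (> 0).
#' @param flow_rate water flow rate FR in ml min^-1 (> 0).
#' @param animal_mass animal fresh weight w_f in g (> 0).
#' @param mixing_delay effective inlet-outlet signal delay in minutes
#'   (0-10); the first-order chamber mixing kernel is parameterised so its
#'   first-moment lag equals this value.
#' @param inflow_po2 inlet oxygen partial pressure in torr; defaults to
#'   air saturation at 12 C and 760 torr.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(volume_l = 1, flow_rate = 200, animal_mass = 330,
                         mixing_delay = 3,
                         inflow_po2 = percent_airsat_to_torr(100, 760, 12)) {
  assert_scalar_num(volume_l, "volume_l")
  if (volume_l <= 0) stop_validation("`volume_l` must be > 0")
  assert_scalar_num(flow_rate, "flow_rate")
  if (flow_rate <= 0) stop_config("`flow_rate` must be > 0")
  assert_scalar_num(animal_mass, "animal_mass")
  if (animal_mass <= 0) stop_validation("`animal_mass` must be > 0")
  assert_scalar_num(mixing_delay, "mixing_delay", lower = 0, upper = 10)
  assert_scalar_num(inflow_po2, "inflow_po2", lower = 0)
  structure(list(volume_l = volume_l, flow_rate = flow_rate,
                 animal_mass = animal_mass, mixing_delay = mixing_delay,
                 inflow_po2 = inflow_po2),
            class = "chamber_spec")
}

#' Simulate inlet/outlet optode traces through a mixed chamber
#'
#' The oxygen deficit the animal imposes on the outflow,
#' `mo2_true * w_f / (alpha_O2 * FR)` torr, is passed through a
#' single-compartment first-order mixing filter whose time constant equals
#' the chamber's `mixing_delay` (so the kernel's first-moment lag matches
#' the observed inlet-outlet delay), subtracted from the constant inflow
#' partial pressure, and overlaid with Gaussian optode noise. The mixing
#' filter has unit gain, so the time integral of the inferred consumption
#' equals the integral of the true consumption (mass conservation).
#'
#' @param profile an [make_activity_profile()] result.
#' @param chamber a [chamber_spec()].
#' @param noise_sd optode noise SD in torr.
#' @param seed integer seed for the noise draws.
#' @param temperature,salinity water conditions used to compute the oxygen
#'   solubility; default to the profile's generating parameters.
#' @param alpha oxygen solubility override in uM torr^-1; computed from
#'   `temperature`/`salinity` when `NULL`.
#' @return Data frame of class `optode_pair` with columns `time_min`,
#'   `inflow_torr`, `outflow_torr`; water temperature and salinity stored as
#'   attributes.
#' @export
make_optode_traces <- function(profile, chamber, noise_sd = 0.3, seed = NULL,
                               temperature = NULL, salinity = 33,
                               alpha = NULL) {
  if (!inherits(profile, "activity_profile"))
    stop_validation("`profile` must be an activity_profile")
  if (!nrow(profile)) stop_validation("`profile` is empty")
  if (!inherits(chamber, "chamber_spec"))
    stop_validation("`chamber` must be a chamber_spec")
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (is.null(temperature)) {
    p <- attr(profile, "params")
    temperature <- if (!is.null(p)) p$temperature else 12
  }
  if (is.null(alpha)) alpha <- oxygen_solubility(temperature, salinity)
  dt <- if (nrow(profile) > 1) diff(profile$time[1:2]) else 1
  deficit <- profile$mo2_true * chamber$animal_mass /
    (alpha * chamber$flow_rate)
  mixed <- first_order_mix(deficit, tau = chamber$mixing_delay, dt = dt)
  with_seed(seed, {
    n <- length(mixed)
    inflow <- rep(chamber$inflow_po2, n)
    outflow <- chamber$inflow_po2 - mixed
    if (noise_sd > 0) {
      inflow <- inflow + stats::rnorm(n, 0, noise_sd)
      outflow <- outflow + stats::rnorm(n, 0, noise_sd)
    }
    out <- data.frame(time_min = profile$time,
                      inflow_torr = inflow,
                      outflow_torr = pmax(outflow, 0))
    attr(out, "temperature") <- temperature
    attr(out, "salinity") <- salinity
    attr(out, "chamber") <- chamber
    class(out) <- c("optode_pair", "data.frame")
    out
  })
}

# Unit-gain first-order (exponential) mixing filter. The pole is placed at
# a = tau/(tau + dt) so the impulse response's first-moment lag equals tau
# exactly in discrete time, and the DC gain is exactly 1 (mass conserved).
#' @keywords internal
first_order_mix <- function(x, tau, dt = 1) {
  if (tau <= 0) return(x)
  a <- tau / (tau + dt)
  # start in steady state at the first value to avoid a spin-up transient
  as.numeric(stats::filter(x * (1 - a), filter = a, method = "recursive",
                           init = x[1]))
}

# Exact inverse of first_order_mix: x_t = (y_t - a*y_{t-1}) / (1 - a).
#' @keywords internal
first_order_unmix <- function(y, tau, dt = 1) {
  if (tau <= 0) return(y)
  a <- tau / (tau + dt)
  x <- (y - a * c(y[1], y[-length(y)])) / (1 - a)
  x
}
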