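#' Parameters of one episodic activity cycle
#'
#' Container for the parameters that define the periodic
#' rise-peak-decline-pause cycle of oxygen consumption, heart rate,
#' ventilation and perfusion displayed by resting decapod crustaceans
#' ("pausing behaviour"). All durations are in minutes, metabolic rates in
#' nmol O2 min^-1 g^-1 fresh weight, heart rates in beats min^-1 and stroke
#' volume in ml beat^-1.
#'
#' @param pulses_per_hour mean number of metabolic pulses per hour (> 0).
#' @param peak_duration,decline_duration,pause_duration,rise_duration nominal
#'   phase durations in minutes. The decline is exponential towards
#'   `mo2_baseline` and occupies whatever time remains of the cycle after the
#'   other phases; `decline_duration` sets its time scale (time to reach
#'   ~2% of the peak-baseline amplitude).
#' @param mo2_baseline,mo2_peak,mo2_pause metabolic-rate levels of the
#'   inter-pulse baseline, the pulse maximum and the pause.
#' @param hr_peak,hr_pause heart-rate levels tracking the metabolic cycle.
#' @param sv_mean mean cardiac stroke volume (ml beat^-1).
#' @param vent_peak,perf_peak peak ventilatory water-flow and sternal-artery
#'   hemolymph-flow velocities (cm s^-1).
#' @param noise_sd Gaussian noise standard deviation added to the metabolic
#'   channel (nmol min^-1 g^-1).
#' @param temperature water temperature in degrees C.
#' @param co2_level `"normocapnia"` or `"hypercapnia"`.
#'
#' @return An object of class `activity_cycle_params` (a named list).
#' @seealso [default_params()] for the temperature/CO2-anchored defaults,
#'   [make_activity_profile()] to generate a trace.
#' @export
activity_cycle_params <- function(pulses_per_hour,
                                  peak_duration, decline_duration,
                                  pause_duration, rise_duration,
                                  mo2_baseline, mo2_peak, mo2_pause = 0,
                                  hr_peak = 60, hr_pause = 2,
                                  sv_mean = 0.2,
                                  vent_peak = 4, perf_peak = 4,
                                  noise_sd = 1.2,
                                  temperature = 12,
                                  co2_level = c("normocapnia", "hypercapnia")) {
  co2_level <- match.arg(co2_level)
  assert_scalar_num(pulses_per_hour, "pulses_per_hour")
  if (pulses_per_hour <= 0) stop_validation("`pulses_per_hour` must be > 0")
  for (nm in c("peak_duration", "decline_duration", "pause_duration",
               "rise_duration")) {
    assert_scalar_num(get(nm), nm, lower = 0)
  }
  assert_scalar_num(mo2_pause, "mo2_pause", lower = 0)
  assert_scalar_num(mo2_baseline, "mo2_baseline", lower = mo2_pause)
  assert_scalar_num(mo2_peak, "mo2_peak", lower = mo2_baseline)
  assert_scalar_num(hr_pause, "hr_pause", lower = 0)
  assert_scalar_num(hr_peak, "hr_peak", lower = hr_pause)
  assert_scalar_num(sv_mean, "sv_mean", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  period <- 60 / pulses_per_hour
  if (rise_duration + peak_duration + pause_duration > period)
    stop_config("phase durations (rise + peak + pause = ",
                rise_duration + peak_duration + pause_duration,
                " min) exceed the cycle period of ", round(period, 2), " min")
  structure(
    list(pulses_per_hour = pulses_per_hour,
         peak_duration = peak_duration,
         decline_duration = decline_duration,
         pause_duration = pause_duration,
         rise_duration = rise_duration,
         mo2_baseline = mo2_baseline,
         mo2_peak = mo2_peak,
         mo2_pause = mo2_pause,
         hr_peak = hr_peak,
         hr_pause = hr_pause,
         sv_mean = sv_mean,
         vent_peak = vent_peak,
         perf_peak = perf_peak,
         noise_sd = noise_sd,
         temperature = temperature,
         co2_level = co2_level),
    class = "activity_cycle_params")
}

# Condition-anchored defaults. Rows are the plateau temperatures of the
# stepwise warming protocol; values are chosen so that synthetic traces
# reproduce the reported phenomenology: ~2 pulses/h at 12 C with <10 min
# maxima, ~10 min declines and ~10 min near-zero pauses; amplitudes rising
# with warming up to a 75 nmol min^-1 g^-1 ceiling (reached already at 12 C
# under hypercapnia); normocapnic pauses shortening with warming (lowest-
# quartile occupancy falling from ~40% to ~17%) while hypercapnic pauses
# stay long (30-50% occupancy); no zero-level pauses at 20 C normocapnia.
.default_grid <- local({
  tt <- c(12, 14, 16, 18, 20)
  norm <- data.frame(
    temperature = tt, co2_level = "normocapnia",
    pulses_per_hour = c(2, 2.5, 3, 3.5, 4),
    rise_duration   = c(2, 2, 1.5, 1.5, 1),
    peak_duration   = c(3.5, 2.7, 2.2, 2, 1.8),
    decline_duration = c(10, 9, 8, 7, 6),
    pause_duration  = c(10, 7, 5, 3.5, 3),
    mo2_baseline = c(10.5, 12, 15, 18, 22),
    mo2_peak     = c(36, 45, 52, 56, 56),
    mo2_pause    = c(0, 0, 0, 0, 4),
    hr_peak  = c(60, 75, 90, 110, 120),
    hr_pause = c(2, 2, 3, 4, 6),
    sv_mean  = c(0.20, 0.22, 0.25, 0.28, 0.30),
    vent_peak = c(4, 4.5, 5, 6, 8),
    perf_peak = c(4, 4.5, 5, 5.5, 6),
    stringsAsFactors = FALSE)
  hyp <- data.frame(
    temperature = tt, co2_level = "hypercapnia",
    pulses_per_hour = c(2, 2.5, 2.5, 3, 3),
    rise_duration   = c(2, 2, 1.5, 1.5, 1.5),
    peak_duration   = c(3.3, 2.6, 2.7, 2.1, 2.1),
    decline_duration = c(10, 9, 9, 8, 8),
    pause_duration  = c(10, 9, 9, 8, 8),
    mo2_baseline = c(20, 20, 21, 22, 23),
    mo2_peak     = c(75, 75, 75, 75, 75),
    mo2_pause    = c(0, 0, 0, 0, 0),
    hr_peak  = c(55, 70, 85, 100, 110),
    hr_pause = c(2, 2, 2, 3, 4),
    sv_mean  = c(0.20, 0.25, 0.30, 0.38, 0.45),
    vent_peak = c(4, 4.2, 4.5, 5, 6),
    perf_peak = c(5, 5.5, 6, 7, 8),
    stringsAsFactors = FALSE)
  rbind(norm, hyp)
})

#' Default cycle parameters for a temperature/CO2 condition
#'
#' Returns the parameter set anchoring the synthetic generator to the study
#' conditions: stepwise warming at 12, 14, 16, 18 and 20 degrees C under
#' normocapnia (~470 uatm CO2) or hypercapnia (~1,350 uatm).
#'
#' @param temperature one of 12, 14, 16, 18, 20 (degrees C).
#' @param co2_level `"normocapnia"` or `"hypercapnia"`.
#' @param noise_sd metabolic-channel noise SD (nmol min^-1 g^-1).
#' @return An [activity_cycle_params()] object.
#' @examples
#' p <- default_params(12, "normocapnia")
#' p$pulses_per_hour  # 2 pulses per hour at 12 C
#' @export
default_params <- function(temperature,
                           co2_level = c("normocapnia", "hypercapnia"),
                           noise_sd = 1.2) {
  co2_level <- match.arg(co2_level)
  row <- .default_grid[.default_grid$temperature == temperature &
                         .default_grid$co2_level == co2_level, ]
  if (nrow(row) != 1L)
    stop_config("no default parameters for temperature = ", temperature,
                ", co2_level = '", co2_level,
                "'; temperature must be one of 12, 14, 16, 18, 20")
  activity_cycle_params(
    pulses_per_hour = row$pulses_per_hour,
    peak_duration = row$peak_duration,
    decline_duration = row$decline_duration,
    pause_duration = row$pause_duration,
    rise_duration = row$rise_duration,
    mo2_baseline = row$mo2_baseline,
    mo2_peak = row$mo2_peak,
    mo2_pause = row$mo2_pause,
    hr_peak = row$hr_peak,
    hr_pause = row$hr_pause,
    sv_mean = row$sv_mean,
    vent_peak = row$vent_peak,
    perf_peak = row$perf_peak,
    noise_sd = noise_sd,
    temperature = temperature,
    co2_level = co2_level)
}

#' @export
print.activity_cycle_params <- function(x, ...) {
  cat("Activity cycle parameters (", x$temperature, "C, ", x$co2_level, ")\n",
      sep = "")
  cat(sprintf("  %g pulses/h; rise %g, peak %g, pause %g min (decline tau %g min)\n",
              x$pulses_per_hour, x$rise_duration, x$peak_duration,
              x$pause_duration, x$decline_duration))
  cat(sprintf("  MO2 pause/baseline/peak: %g / %g / %g nmol min^-1 g^-1\n",
              x$mo2_pause, x$mo2_baseline, x$mo2_peak))
  cat(sprintf("  HR pause/peak: %g / %g bpm; SV %g ml; noise SD %g\n",
              x$hr_pause, x$hr_peak, x$sv_mean, x$noise_sd))
  invisible(x)
}
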