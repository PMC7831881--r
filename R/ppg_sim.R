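#' Simulate an infra-red photoplethysmography voltage trace
#'
#' Emits a cardiac pulse train whose instantaneous rate follows the
#' profile's `hr_true` and whose per-beat waveform area is proportional to
#' `sv_true`. Each beat is a raised-cosine pulse of fixed width; the pulse
#' amplitude is set so the waveform area above baseline equals
#' `gain * sv_true` volt-seconds per beat. Gaussian sensor noise is added
#' on top of a zero baseline.
#'
#' @param profile an [make_activity_profile()] result (1 min^-1 channels).
#' @param sampling_rate samples per second, >= 100 Hz.
#' @param pulse_width raised-cosine pulse width in seconds.
#' @param gain volt-seconds of waveform area per ml of stroke volume.
#' @param noise_sd sensor noise SD in volts.
#' @param seed integer seed.
#' @return Data frame of class `ppg_trace` with columns `time_s`,
#'   `voltage`; the sampling rate is stored in `attr(, "sampling_rate")`.
#' @export
make_ppg_trace <- function(profile, sampling_rate = 100, pulse_width = 0.25,
                           gain = 1, noise_sd = 0.01, seed = NULL) {
  if (!inherits(profile, "activity_profile"))
    stop_validation("`profile` must be an activity_profile")
  if (sampling_rate < 100)
    stop_validation("`sampling_rate` must be >= 100 Hz")
  if (max(profile$hr_true) / 60 > sampling_rate / 2)
    stop_config("heart rate exceeds half the sampling rate")
  dt_min <- if (nrow(profile) > 1) diff(profile$time[1:2]) else 1
  total_s <- nrow(profile) * dt_min * 60
  n <- round(total_s * sampling_rate)
  time_s <- (seq_len(n) - 1) / sampling_rate

  # per-sample heart rate / stroke volume (step interpolation of the
  # minute-resolution truth)
  idx <- pmin(floor(time_s / 60 / dt_min) + 1L, nrow(profile))
  hr_s <- profile$hr_true[idx]
  sv_s <- profile$sv_true[idx]

  # cardiac phase accumulates at hr/60 cycles per second; a beat fires at
  # every integer crossing
  phase <- cumsum(hr_s / 60 / sampling_rate)
  kfloor <- floor(phase + 1e-12)
  onset <- which(kfloor > c(0L, kfloor[-n]))

  voltage <- numeric(n)
  wlen <- max(round(pulse_width * sampling_rate), 2L)
  # raised cosine with unit area, scaled per beat
  shape <- (1 - cos(2 * pi * (seq_len(wlen) - 0.5) / wlen)) / 2
  shape <- shape / (sum(shape) / sampling_rate)
  for (b in onset) {
    j <- b:min(b + wlen - 1L, n)
    voltage[j] <- voltage[j] + gain * sv_s[b] * shape[seq_along(j)]
  }

  with_seed(seed, {
    if (noise_sd > 0) voltage <- voltage + stats::rnorm(n, 0, noise_sd)
    out <- data.frame(time_s = time_s, voltage = voltage)
    attr(out, "sampling_rate") <- sampling_rate
    attr(out, "onsets") <- time_s[onset] # ground-truth beat onsets
    class(out) <- c("ppg_trace", "data.frame")
    out
  })
}

#' Construct a PPG trace from raw samples
#'
#' @param time_s sample times in seconds (uniform).
#' @param voltage sensor voltage.
#' @param sampling_rate samples per second (>= 100); inferred from `time_s`
#'   when missing.
#' @return a `ppg_trace` data frame.
#' @export
ppg_trace <- function(time_s, voltage, sampling_rate = NULL) {
  if (length(time_s) != length(voltage))
    stop_validation("`time_s` and `voltage` differ in length")
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(time_s))
    # absorb floating-point wobble in stored timestamps
    if (abs(sampling_rate - round(sampling_rate)) < 1e-6 * sampling_rate)
      sampling_rate <- round(sampling_rate)
  }
  if (sampling_rate < 100)
    stop_validation("`sampling_rate` must be >= 100 Hz")
  out <- data.frame(time_s = time_s, voltage = voltage)
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("ppg_trace", "data.frame")
  out
}

#' @export
print.ppg_trace <- function(x, ...) {
  cat(sprintf("PPG trace: %d samples at %g Hz (%.1f min), voltage %.3f-%.3f V\n",
              nrow(x), attr(x, "sampling_rate"), max(x$time_s) / 60,
              min(x$voltage), max(x$voltage)))
  invisible(x)
}
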