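# Shared fixtures, built in code.

# parameters for a flat (constant-level) profile: every channel constant,
# useful for steady-state and zero-consumption identities
flat_params <- function(level = 10, hr = 60, sv = 0.2, noise_sd = 0) {
  activity_cycle_params(
    pulses_per_hour = 1, peak_duration = 0, decline_duration = 1,
    pause_duration = 0, rise_duration = 0,
    mo2_baseline = level, mo2_peak = level, mo2_pause = level,
    hr_peak = hr, hr_pause = hr, sv_mean = sv, noise_sd = noise_sd)
}

flat_profile <- function(duration_h, level = 10, hr = 60, sv = 0.2,
                         noise_sd = 0, seed = 1) {
  make_activity_profile(flat_params(level, hr, sv, noise_sd), duration_h,
                        seed = seed, elevated_rate = 0,
                        baseline_wander_cv = 0)
}

# rectangular pulse train as a raw PPG trace: amplitude in volts, width and
# period in seconds
pulse_train_trace <- function(amplitude = 1, width = 0.1, period = 1,
                              duration_s = 60, rate = 100) {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  phase <- t %% period
  v <- ifelse(phase < width, amplitude * sin(pi * phase / width), 0)
  ppg_trace(t, v, sampling_rate = rate)
}

# brute-force modified-Z flags, written independently of the package code
brute_modified_z <- function(x, threshold = 3.5) {
  med <- median(x)
  mad0 <- median(abs(x - med))
  abs(0.6745 * (x - med) / mad0) >= threshold
}
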