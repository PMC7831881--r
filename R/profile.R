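#' Generate a synthetic episodic activity profile
#'
#' Simulates the ground-truth physiological state of a resting crab over
#' time: whole-animal oxygen consumption (MO2), heart rate, stroke volume,
#' ventilatory water flow and sternal-artery perfusion, organised in
#' repeating rise-peak-decline-pause cycles ("pausing behaviour"). Sampling
#' is 1 min^-1 by default, matching flow-through respirometry practice.
#'
#' Each cycle draws its phase durations from a lognormal jitter
#' distribution (CV 0.2) around the nominal durations in `params`, and its
#' pulse amplitude uniformly from 92-100% of `mo2_peak`, so pulse maxima are
#' consistent across cycles and the tallest pulses define the range ceiling.
#' The decline is exponential towards `mo2_baseline` (rate such that the
#' nominal `decline_duration` covers ~98% of the drop) and fills all cycle
#' time not taken by rise, peak and pause. Heart rate, ventilation and
#' perfusion co-fluctuate with the metabolic cycle, so pauses are
#' accompanied by bradycardia and hypoventilation. Episodes of spontaneously
#' elevated activity (activity held high for >= 2 h) can be inserted at a
#' configurable Poisson rate.
#'
#' @param params an [activity_cycle_params()] object.
#' @param duration_h record length in hours (> 0).
#' @param seed integer seed; identical `(params, duration_h, seed)` give
#'   identical output. `NULL` uses the current RNG state.
#' @param elevated_rate Poisson rate (h^-1) of spontaneously elevated
#'   activity episodes (each 2-4 h long). Default 0.05 h^-1.
#' @param baseline_wander_cv coefficient of variation of the slow
#'   per-cycle lognormal wander of the inter-pulse baseline (default 0.12;
#'   set to 0 for a fixed baseline).
#' @param dt_min sampling interval in minutes.
#' @return A data frame of class `activity_profile` with columns `time`
#'   (minutes from start), `mo2_true`, `hr_true`, `sv_true`, `vent_true`,
#'   `perf_true` and `phase_label` (factor: rise, peak, decline, pause,
#'   elevated). The generating parameters are stored in
#'   `attr(, "params")`.
#' @examples
#' prof <- make_activity_profile(default_params(12, "normocapnia"),
#'                               duration_h = 10, seed = 1)
#' table(prof$phase_label)
#' @export
make_activity_profile <- function(params, duration_h, seed = NULL,
                                  elevated_rate = 0.05,
                                  baseline_wander_cv = 0.12, dt_min = 1) {
  if (!inherits(params, "activity_cycle_params"))
    stop_validation("`params` must be an activity_cycle_params object")
  assert_scalar_num(duration_h, "duration_h")
  if (duration_h <= 0) stop_validation("`duration_h` must be > 0")
  assert_scalar_num(elevated_rate, "elevated_rate", lower = 0)

  total_min <- duration_h * 60
  period <- 60 / params$pulses_per_hour
  if (params$rise_duration + params$peak_duration + params$pause_duration >
      period)
    stop_config("phase durations exceed the cycle period")

  with_seed(seed, {
    segs <- .build_cycle_segments(params, total_min, baseline_wander_cv)
    if (elevated_rate > 0)
      elevated <- .draw_elevated_episodes(elevated_rate, total_min)
    else
      elevated <- NULL

    time <- seq(0, total_min - dt_min, by = dt_min)
    mo2 <- numeric(length(time))
    phase <- character(length(time))
    idx <- findInterval(time, segs$start)
    for (s in seq_len(nrow(segs))) {
      in_s <- which(idx == s)
      if (!length(in_s)) next
      t_rel <- time[in_s] - segs$start[s]
      mo2[in_s] <- switch(
        segs$type[s],
        rise = segs$from[s] + (segs$to[s] - segs$from[s]) *
          t_rel / max(segs$end[s] - segs$start[s], dt_min),
        peak = segs$to[s],
        decline = segs$to[s] + (segs$from[s] - segs$to[s]) *
          exp(-segs$rate[s] * t_rel),
        pause = segs$to[s])
      phase[in_s] <- segs$type[s]
    }

    if (!is.null(elevated) && nrow(elevated)) {
      lvl <- params$mo2_baseline +
        0.75 * (params$mo2_peak - params$mo2_baseline)
      for (e in seq_len(nrow(elevated))) {
        in_e <- which(time >= elevated$start[e] & time < elevated$end[e])
        if (!length(in_e)) next
        # slow sinusoidal wander keeps the rolling minimum well above range mid
        mo2[in_e] <- lvl * (1 + 0.1 * sin(2 * pi * time[in_e] / 90))
        phase[in_e] <- "elevated"
      }
    }

    # activity index drives the coupled channels
    span <- max(params$mo2_peak - params$mo2_pause, 1e-9)
    act <- pmin(pmax((mo2 - params$mo2_pause) / span, 0), 1)
    hr <- params$hr_pause + (params$hr_peak - params$hr_pause) * act
    vent <- params$vent_peak * act
    perf <- 0.15 * params$perf_peak + 0.85 * params$perf_peak * act
    sv <- params$sv_mean * (0.8 + 0.4 * act)

    n <- length(time)
    if (params$noise_sd > 0) {
      mo2 <- pmax(mo2 + stats::rnorm(n, 0, params$noise_sd), 0)
      hr <- pmax(hr + stats::rnorm(n, 0, 0.02 * params$hr_peak), 0)
      vent <- pmax(vent + stats::rnorm(n, 0, 0.03 * params$vent_peak), 0)
      perf <- pmax(perf + stats::rnorm(n, 0, 0.03 * params$perf_peak), 0)
      sv <- pmax(sv + stats::rnorm(n, 0, 0.02 * params$sv_mean), 0)
    }

    out <- data.frame(
      time = time,
      mo2_true = mo2,
      hr_true = hr,
      sv_true = sv,
      vent_true = vent,
      perf_true = perf,
      phase_label = factor(phase, levels = c("rise", "peak", "decline",
                                             "pause", "elevated")),
      stringsAsFactors = FALSE)
    attr(out, "params") <- params
    class(out) <- c("activity_profile", "data.frame")
    out
  })
}

# Draw jittered cycles until `total_min` is covered; return a segment table
# with columns start, end, type, from, to, rate.
#' @keywords internal
.build_cycle_segments <- function(params, total_min, baseline_wander_cv = 0.12) {
  period <- 60 / params$pulses_per_hour
  n_cycles <- ceiling(total_min / period) + 3L
  r <- rlnorm_mean_cv(n_cycles, params$rise_duration, 0.2)
  k <- rlnorm_mean_cv(n_cycles, params$peak_duration, 0.2)
  u <- rlnorm_mean_cv(n_cycles, params$pause_duration, 0.2)
  p <- rlnorm_mean_cv(n_cycles, period, 0.2)
  # pulse amplitude above baseline varies mildly; the tallest pulses define
  # the range ceiling
  amp <- params$mo2_baseline + (params$mo2_peak - params$mo2_baseline) *
    stats::runif(n_cycles, 0.92, 1)
  # slow physiological wander of the inter-pulse baseline
  base <- if (baseline_wander_cv > 0 && params$mo2_baseline > 0)
    rlnorm_mean_cv(n_cycles, params$mo2_baseline, baseline_wander_cv)
  else rep(params$mo2_baseline, n_cycles)
  # keep the jittered phases inside the jittered period
  over <- (r + k + u) > 0.9 * p
  if (any(over)) {
    f <- 0.9 * p[over] / (r + k + u)[over]
    r[over] <- r[over] * f; k[over] <- k[over] * f; u[over] <- u[over] * f
  }
  d <- p - r - k - u # decline + baseline residence
  rate <- 4 / max(params$decline_duration, 0.5)

  segs <- vector("list", n_cycles)
  t0 <- 0
  for (i in seq_len(n_cycles)) {
    segs[[i]] <- data.frame(
      start = t0 + c(0, r[i], r[i] + k[i], r[i] + k[i] + d[i]),
      end = t0 + c(r[i], r[i] + k[i], r[i] + k[i] + d[i], p[i]),
      type = c("rise", "peak", "decline", "pause"),
      from = c(params$mo2_pause, amp[i], amp[i], params$mo2_pause),
      to = c(amp[i], amp[i], base[i], params$mo2_pause),
      rate = c(NA, NA, rate, NA),
      stringsAsFactors = FALSE)
    t0 <- t0 + p[i]
  }
  segs <- do.call(rbind, segs)
  segs[segs$start < total_min, , drop = FALSE]
}

#' @keywords internal
.draw_elevated_episodes <- function(rate_per_h, total_min) {
  n <- stats::rpois(1, rate_per_h * total_min / 60)
  if (n == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  start <- sort(stats::runif(n, 0, max(total_min - 120, 0)))
  dur <- stats::runif(n, 120, 240) # >= 2 h episodes
  data.frame(start = start, end = pmin(start + dur, total_min))
}

#' @export
print.activity_profile <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Synthetic activity profile: %d samples (%.1f h at %g min^-1)\n",
              nrow(x), max(x$time) / 60, 1 / diff(x$time[1:2])))
  if (!is.null(p))
    cat(sprintf("  %g C, %s; %g pulses/h nominal\n",
                p$temperature, p$co2_level, p$pulses_per_hour))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' @export
plot.activity_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time / 60, x$mo2_true, type = "l", xlab = "time (h)",
                 ylab = "MO2 (nmol min^-1 g^-1)", ...)
  graphics::plot(x$time / 60, x$hr_true, type = "l", xlab = "time (h)",
                 ylab = "HR (bpm)", ...)
  invisible(x)
}
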