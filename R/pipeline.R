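#' Define an emulated warming experiment
#'
#' The default design mirrors the stepwise warming protocol: plateau phases
#' at 12, 14, 16, 18 and 20 C under one CO2 level, with only the last
#' `analysis_window` hours of each plateau analysed.
#'
#' @param animals data frame with columns `id` and `mass` (g), or a number
#'   of animals to auto-generate (masses drawn around 330 g at run time).
#' @param temperature_steps data frame with columns `temperature` (C) and
#'   `hours` (plateau length); default 10 h at each of 12-20 C.
#' @param co2_level `"normocapnia"`, `"hypercapnia"` or `"both"`.
#' @param flow_rate chamber flow rate, ml min^-1.
#' @param analysis_window last-N hours of each plateau to analyse
#'   (default 5).
#' @param mixing_delay chamber mixing delay in minutes.
#' @param seawater measured water chemistry per CO2 level: data frame with
#'   columns `co2_level`, `pco2` (uatm), `ph`, `temperature`, `salinity`;
#'   defaults to the treatment waters of the warming protocol.
#' @param seed integer seed for the whole experiment.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(animals = 4,
                              temperature_steps = NULL,
                              co2_level = "both",
                              flow_rate = 200,
                              analysis_window = 5,
                              mixing_delay = 3,
                              seawater = NULL,
                              seed = 1) {
  if (is.numeric(animals) && length(animals) == 1) {
    animals <- data.frame(id = paste0("crab", seq_len(animals)),
                          mass = 330 + 10 * seq_len(animals) - 25)
  }
  if (!all(c("id", "mass") %in% names(animals)))
    stop_validation("`animals` must have columns id and mass")
  if (is.null(temperature_steps))
    temperature_steps <- data.frame(temperature = c(12, 14, 16, 18, 20),
                                    hours = 10)
  if (!all(c("temperature", "hours") %in% names(temperature_steps)))
    stop_validation("`temperature_steps` needs columns temperature, hours")
  if (any(temperature_steps$hours < analysis_window))
    stop_validation("analysis_window exceeds a plateau duration")
  co2 <- match.arg(co2_level, c("normocapnia", "hypercapnia", "both"))
  co2 <- if (co2 == "both") c("normocapnia", "hypercapnia") else co2
  if (is.null(seawater))
    seawater <- data.frame(
      co2_level = c("normocapnia", "hypercapnia"),
      pco2 = c(478, 1379), ph = c(8.06, 7.61),
      temperature = c(11.85, 11.50), salinity = c(32.75, 32.92))
  structure(list(animals = animals,
                 temperature_steps = temperature_steps,
                 co2_levels = co2,
                 flow_rate = flow_rate,
                 analysis_window = analysis_window,
                 mixing_delay = mixing_delay,
                 seawater = seawater,
                 seed = seed),
            class = "experiment_design")
}

#' Run an emulated experiment end to end
#'
#' For every animal, CO2 level and temperature plateau the pipeline
#' simulates the truth profile and optode pair, computes the metabolic
#' trace (with mixing deconvolution at the design's chamber delay),
#' restricts to the last `analysis_window` hours, excludes elevated-activity
#' phases, screens outliers and computes quartile occupancy and pulse
#' rates; finally the inference layer is run on the pooled occupancy table.
#' Identical designs and seeds produce identical bundles.
#'
#' @param design an [experiment_design()].
#' @param out_dir optional directory; when given, `occupancy.csv`,
#'   `pulse_rates.csv`, `mo2.csv`, `beats.csv`, `flows_summary.csv`,
#'   `ventperf.csv`, `carbonate.csv`, `stats_report.json` and
#'   `provenance.json` are written there.
#' @param quiet suppress per-stage progress lines.
#' @return list with `occupancy` (one row per animal x temperature x CO2),
#'   `pulse_rates`, `beats` (exemplar per-minute cardiac table per CO2
#'   level), `flow_summary` and `ventperf` (aggregated vessel flows and the
#'   ventilation-perfusion correlation), `carbonate` (treatment water
#'   chemistry), `stats` (mixed model fit, Tukey contrasts, rank tests)
#'   and `design`.
#' @export
run_experiment <- function(design, out_dir = NULL, quiet = TRUE) {
  if (!inherits(design, "experiment_design"))
    stop_validation("`design` must be an experiment_design")
  say <- function(...) if (!quiet) message(sprintf(...))

  occ <- list()
  pulses <- list()
  mo2_tabs <- list()
  # individual metabolic scope: a per-animal multiplier on the cycle levels,
  # giving the random-intercept structure the inference layer models
  animal_scale <- with_seed(design$seed,
                            rlnorm_mean_cv(nrow(design$animals), 1, 0.1))
  combo_seed <- 0L
  for (co2 in design$co2_levels) {
    for (ai in seq_len(nrow(design$animals))) {
      animal <- design$animals$id[ai]
      mass <- design$animals$mass[ai]
      mo2_rows <- list()
      for (si in seq_len(nrow(design$temperature_steps))) {
        temp <- design$temperature_steps$temperature[si]
        hrs <- design$temperature_steps$hours[si]
        combo_seed <- combo_seed + 1L
        seed_i <- (design$seed * 10007L + combo_seed * 101L) %% .Machine$integer.max

        params <- default_params(temp, co2)
        for (nm in c("mo2_baseline", "mo2_peak", "mo2_pause"))
          params[[nm]] <- params[[nm]] * animal_scale[ai]
        prof <- make_activity_profile(params, duration_h = hrs,
                                      seed = seed_i)
        chamber <- chamber_spec(flow_rate = design$flow_rate,
                                animal_mass = mass,
                                mixing_delay = design$mixing_delay)
        pair <- make_optode_traces(prof, chamber, noise_sd = 0.05,
                                   seed = seed_i + 1L)
        mt <- compute_mo2(pair, design$flow_rate, mass,
                          delay = design$mixing_delay, deconvolve = TRUE)

        # elevated phases are judged on the whole plateau record, then the
        # analysis restricts to the last N hours
        keep_full <- exclude_elevated_phases(mt$mo2)
        t_end <- max(mt$time)
        win <- mt$time > t_end - design$analysis_window * 60
        mo2_w <- mt$mo2[win]
        keep <- keep_full[win]
        mo2_kept <- mo2_w[keep]
        if (length(mo2_kept) < 60) {
          # an elevated episode consumed the analysis window; fall back to
          # all fluctuating activity of the plateau
          say("window at %g C %s mostly elevated; using the whole plateau",
              temp, co2)
          mo2_w <- mt$mo2
          keep <- keep_full
          mo2_kept <- mo2_w[keep]
          win <- rep(TRUE, length(mt$mo2))
        }
        if (length(mo2_kept) < 60)
          stop_validation("fewer than 60 fluctuating-activity samples for ",
                          animal, " at ", temp, " C ", co2)
        res <- quartile_occupancy(mo2_kept, animal_id = animal,
                                  temperature = temp, co2_level = co2)
        occ[[length(occ) + 1L]] <- res
        # pulse rate needs >= 2 h of retained fluctuating activity
        pph <- if (length(mo2_kept) >= 121)
          as.numeric(count_pulses(mo2_kept)) else NA_real_
        pulses[[length(pulses) + 1L]] <- data.frame(
          animal_id = animal, temperature = temp, co2_level = co2,
          pulses_per_hour = pph)
        mo2_rows[[si]] <- data.frame(animal_id = animal, temperature = temp,
                                     co2_level = co2,
                                     time_min = mt$time[win],
                                     mo2_nmol_min_g = mo2_w,
                                     kept = keep)
        say("animal %s %s %g C: %d samples kept, frac_low %.2f",
            animal, co2, temp, res$n_samples, res$frac_low)
      }
      mo2_tabs[[length(mo2_tabs) + 1L]] <- do.call(rbind, mo2_rows)
    }
  }
  occupancy <- do.call(rbind, occ)
  pulse_rates <- do.call(rbind, pulses)
  mo2_all <- do.call(rbind, mo2_tabs)

  # cardiovascular and flow stages on one exemplar recording per CO2 level
  # (15 min of PPG at 100 Hz and the matching flow table), plus the water
  # carbonate chemistry of each treatment
  cardio <- list()
  flow_sum <- list()
  ventperf <- list()
  for (ci in seq_along(design$co2_levels)) {
    co2 <- design$co2_levels[ci]
    seedc <- (design$seed * 10007L + 7777L + ci) %% .Machine$integer.max
    temp0 <- design$temperature_steps$temperature[1]
    profc <- make_activity_profile(default_params(temp0, co2),
                                   duration_h = 0.25, seed = seedc,
                                   elevated_rate = 0)
    tr <- make_ppg_trace(profc, sampling_rate = 100, seed = seedc + 1L)
    bt <- analyze_ppg(tr, reference_mask = seq_len(nrow(profc)))
    bt$animal_id <- design$animals$id[1]
    bt$co2_level <- co2
    cardio[[ci]] <- bt
    say("cardio stage %s: %d minutes, k = %.1f", co2, nrow(bt),
        bt$threshold_k[1])

    flc <- make_flow_series(profc, seed = seedc + 2L)
    agg <- aggregate_branchial(flc)
    agg$co2_level <- co2
    flow_sum[[ci]] <- agg
    vp <- vent_perf_correlation(agg$ventilation_sum, agg$branchial_sum)
    ventperf[[ci]] <- cbind(data.frame(co2_level = co2),
                            as.data.frame(vp))
  }
  beat_table <- do.call(rbind, cardio)
  flow_summary <- do.call(rbind, flow_sum)
  ventperf <- do.call(rbind, ventperf)
  carbonate <- do.call(rbind, lapply(seq_len(nrow(design$seawater)),
    function(i) {
      w <- design$seawater[i, ]
      if (!w$co2_level %in% design$co2_levels) return(NULL)
      as.data.frame(unclass(solve_carbonate(w$pco2, w$ph, w$temperature,
                                            w$salinity)))
    }))

  # inference layer on the pooled per-sample MO2 and the occupancy table
  stats_out <- list()
  mo2_all$value <- standardize(mo2_all$mo2_nmol_min_g)
  fit <- fit_activity_lmm(mo2_all[mo2_all$kept, ])
  stats_out$lmm <- fit
  stats_out$tukey <- tukey_pairwise(fit)
  if (length(design$co2_levels) == 2) {
    stats_out$frac_low_wilcoxon <- lapply(
      split(occupancy, occupancy$temperature),
      function(d) wilcoxon_rank_sum(
        d$frac_low[d$co2_level == "normocapnia"],
        d$frac_low[d$co2_level == "hypercapnia"]))
  }
  stats_out$frac_low_kruskal <- lapply(
    split(occupancy, occupancy$co2_level),
    function(d) kruskal_wallis(d$frac_low, d$temperature))

  bundle <- list(occupancy = occupancy, pulse_rates = pulse_rates,
                 beats = beat_table, flow_summary = flow_summary,
                 ventperf = ventperf, carbonate = carbonate,
                 stats = stats_out, design = design)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(occupancy, file.path(out_dir, "occupancy.csv"),
                     row.names = FALSE)
    utils::write.csv(pulse_rates, file.path(out_dir, "pulse_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(mo2_all, file.path(out_dir, "mo2.csv"),
                     row.names = FALSE)
    utils::write.csv(beat_table, file.path(out_dir, "beats.csv"),
                     row.names = FALSE)
    utils::write.csv(flow_summary, file.path(out_dir, "flows_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(ventperf, file.path(out_dir, "ventperf.csv"),
                     row.names = FALSE)
    utils::write.csv(carbonate, file.path(out_dir, "carbonate.csv"),
                     row.names = FALSE)
    report <- list(
      fixed_effects = stats_out$lmm$fixed,
      lrt_interaction = stats_out$lmm$lrt_interaction,
      tukey = as.data.frame(stats_out$tukey),
      kruskal_frac_low = stats_out$frac_low_kruskal,
      wilcoxon_frac_low = stats_out$frac_low_wilcoxon)
    jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    prov <- list(package = "pauseflow",
                 version = as.character(utils::packageVersion("pauseflow")),
                 seed = design$seed,
                 animals = design$animals,
                 temperature_steps = design$temperature_steps,
                 co2_levels = design$co2_levels,
                 analysis_window_h = design$analysis_window,
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  bundle
}
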