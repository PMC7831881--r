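test_that("condition defaults match the reported cycle phenomenology", {
  p12 <- default_params(12, "normocapnia")
  expect_equal(p12$pulses_per_hour, 2)
  expect_equal(p12$pause_duration, 10)
  expect_lt(p12$peak_duration, 10)
  expect_lt(p12$rise_duration, p12$decline_duration) # fast rise, slow decline

  expect_equal(default_params(12, "hypercapnia")$mo2_peak, 75)
  expect_gt(default_params(20, "normocapnia")$mo2_pause, 0)
  expect_lte(max(sapply(c(12, 14, 16, 18, 20), function(t)
    default_params(t, "hypercapnia")$mo2_peak)), 75)

  # warming increases pulse rate and amplitude under normocapnia
  pn <- lapply(c(12, 16, 20), default_params, co2_level = "normocapnia")
  expect_true(all(diff(sapply(pn, `[[`, "pulses_per_hour")) > 0))
  expect_true(all(diff(sapply(pn, `[[`, "mo2_peak")) >= 0))
  expect_true(all(diff(sapply(pn, `[[`, "pause_duration")) < 0))

  expect_error(default_params(13, "normocapnia"), class = "pauseflow_config_error")
})

test_that("cycle parameter invariants are enforced", {
  expect_error(activity_cycle_params(
    pulses_per_hour = 4, peak_duration = 5, decline_duration = 5,
    pause_duration = 9, rise_duration = 2, mo2_baseline = 10,
    mo2_peak = 30), class = "pauseflow_config_error")
  expect_error(activity_cycle_params(
    pulses_per_hour = 2, peak_duration = 2, decline_duration = 5,
    pause_duration = 5, rise_duration = 2, mo2_baseline = 5,
    mo2_peak = 30, mo2_pause = 8), class = "pauseflow_validation_error")
})

test_that("activity profile pulses at the expected hourly rate", {
  prof <- make_activity_profile(default_params(12, "normocapnia"),
                                duration_h = 10, seed = 1,
                                elevated_rate = 0)
  n_pulses <- as.numeric(count_pulses(prof$mo2_true)) * 10
  expect_gte(n_pulses, 10)
  expect_lte(n_pulses, 30)
  expect_true(all(prof$mo2_true >= 0))
  expect_true(!anyNA(prof$phase_label))
  expect_true(all(diff(prof$time) > 0))
})

test_that("noiseless zero-level pauses give an exact zero floor", {
  p <- default_params(12, "normocapnia", noise_sd = 0)
  prof <- make_activity_profile(p, 5, seed = 2, elevated_rate = 0)
  expect_identical(min(prof$mo2_true), 0)
})

test_that("profiles are deterministic in the seed, not in the path", {
  p <- default_params(12, "normocapnia")
  a <- make_activity_profile(p, 20, seed = 7)
  b <- make_activity_profile(p, 20, seed = 7)
  expect_identical(a, b)

  c2 <- make_activity_profile(p, 20, seed = 8)
  expect_false(identical(a$mo2_true, c2$mo2_true))
  # same phase-duration distribution across seeds: compare pause run lengths
  runs <- function(x) {
    r <- rle(as.vector(x$phase_label == "pause"))
    r$lengths[r$values]
  }
  ks <- suppressWarnings(stats::ks.test(runs(a), runs(c2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("pause occupancy of the 12 C default truth is 30-45% of time", {
  p <- default_params(12, "normocapnia")
  prof <- make_activity_profile(p, 20, seed = 3, elevated_rate = 0)
  frac <- mean(prof$phase_label == "pause")
  expect_gte(frac, 0.30)
  expect_lte(frac, 0.45)
})

test_that("cardiac and ventilatory channels pause with the metabolism", {
  prof <- make_activity_profile(default_params(12, "normocapnia"), 10,
                                seed = 4, elevated_rate = 0)
  pause <- prof$phase_label == "pause"
  peak <- prof$phase_label == "peak"
  expect_lt(mean(prof$hr_true[pause]), 0.2 * mean(prof$hr_true[peak]))
  expect_lt(mean(prof$vent_true[pause]), 0.2 * mean(prof$vent_true[peak]))
})

test_that("zero-consumption animals leave outflow equal to inflow", {
  prof <- flat_profile(2, level = 0)
  ch <- chamber_spec(flow_rate = 200, animal_mass = 330, mixing_delay = 3)
  op <- make_optode_traces(prof, ch, noise_sd = 0)
  expect_equal(op$outflow_torr, op$inflow_torr, tolerance = 1e-12)
})

test_that("steady-state optode deficit follows the respirometry equation", {
  # constant 5.152 nmol/min/g, 330 g, 200 ml/min, alpha 1.7 -> deltaP 5 torr
  prof <- flat_profile(2, level = 5.152)
  ch <- chamber_spec(flow_rate = 200, animal_mass = 330, mixing_delay = 3)
  op <- make_optode_traces(prof, ch, noise_sd = 0, alpha = 1.7)
  expect_equal(unique(round(op$inflow_torr - op$outflow_torr, 3)), 5)
})

test_that("mixing kernel delays by its first moment and conserves mass", {
  # step response centroid equals the nominal 3-min delay
  prof <- flat_profile(4, level = 2)
  prof$mo2_true <- ifelse(prof$time < 120, 2, 12)
  ch <- chamber_spec(flow_rate = 200, animal_mass = 330, mixing_delay = 3)
  op <- make_optode_traces(prof, ch, noise_sd = 0)
  def <- op$inflow_torr - op$outflow_torr
  resp <- diff(def[120:150]) # step occurs at sample 121
  centroid <- sum((seq_along(resp) - 2) * resp) / sum(resp)
  expect_equal(centroid, 3, tolerance = 0.5)

  # conservation over a long noiseless fluctuating run
  prof2 <- make_activity_profile(default_params(12, noise_sd = 0), 10,
                                 seed = 5, elevated_rate = 0)
  op2 <- make_optode_traces(prof2, ch, noise_sd = 0)
  alpha <- oxygen_solubility(12, 33)
  lhs <- sum(op2$inflow_torr - op2$outflow_torr) * alpha * 200
  rhs <- sum(prof2$mo2_true) * 330
  expect_equal(lhs / rhs, 1, tolerance = 0.01)
})

test_that("PPG pulse train carries rate and per-beat area", {
  prof <- flat_profile(1 / 60, hr = 60) # one minute
  tr <- make_ppg_trace(prof, 100, noise_sd = 0, seed = 1)
  expect_length(attr(tr, "onsets"), 60)

  # doubling stroke volume doubles the per-minute waveform integral
  tr1 <- make_ppg_trace(flat_profile(1 / 60, hr = 60, sv = 0.2), 100,
                        noise_sd = 0, seed = 1)
  tr2 <- make_ppg_trace(flat_profile(1 / 60, hr = 60, sv = 0.4), 100,
                        noise_sd = 0, seed = 1)
  int1 <- sum(tr1$voltage - min(tr1$voltage)) / 100
  int2 <- sum(tr2$voltage - min(tr2$voltage)) / 100
  expect_equal(int2 / int1, 2, tolerance = 0.01)

  # no beats are emitted while the heart is stopped
  trz <- make_ppg_trace(flat_profile(1 / 60, hr = 0), 100, noise_sd = 0,
                        seed = 1)
  expect_length(attr(trz, "onsets"), 0)
  expect_identical(unique(trz$voltage), 0)
})

test_that("flow table couples perfusion to ventilation and pauses one side", {
  prof <- make_activity_profile(default_params(12, "normocapnia"), 5,
                                seed = 6, elevated_rate = 0)
  fl <- make_flow_series(prof, coupling_slope = 0.6, coupling_noise = 0,
                         seed = 1)
  vent <- abs(fl$velocity_cm_s[fl$vessel == "excurrent_channel" &
                                 fl$side == "left"]) +
    abs(fl$velocity_cm_s[fl$vessel == "excurrent_channel" &
                           fl$side == "right"])
  bran <- fl$velocity_cm_s[fl$vessel == "branchial_6" & fl$side == "left"] +
    fl$velocity_cm_s[fl$vessel == "branchial_6" & fl$side == "right"]
  expect_equal(unname(cor(vent, bran)), 1, tolerance = 1e-10)

  # sternal artery velocities mostly below 2 cm/s at 12 C
  stern <- fl$velocity_cm_s[fl$vessel == "arteria_sternalis"]
  expect_gt(mean(stern < 2), 0.5)

  # unilateral ventilation during pauses: one excurrent side exactly zero
  fln <- make_flow_series(prof, coupling_slope = 0.6, coupling_noise = 0.1,
                          seed = 2)
  exl <- fln$velocity_cm_s[fln$vessel == "excurrent_channel" &
                             fln$side == "left"]
  exr <- fln$velocity_cm_s[fln$vessel == "excurrent_channel" &
                             fln$side == "right"]
  pause <- prof$phase_label == "pause"
  expect_true(all(pmin(abs(exl[pause]), abs(exr[pause])) == 0))
  # forward ventilation encoded as negative excurrent velocity
  expect_lte(max(exl), 0)
})

test_that("recordings round-trip through the CSV writers", {
  prof <- make_activity_profile(default_params(12), 1, seed = 1)
  ch <- chamber_spec()
  op <- make_optode_traces(prof, ch, seed = 1)
  tr <- make_ppg_trace(prof, 100, seed = 1)
  fl <- make_flow_series(prof, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_recordings(dir, prof, op, tr, fl, seed = 1)
  expect_true(all(file.exists(file.path(
    dir, c("truth.csv", "params.json", "optode.csv", "ppg.csv",
           "flows.csv")))))
  op2 <- read_optode_csv(file.path(dir, "optode.csv"))
  expect_equal(op2$outflow_torr, op$outflow_torr, tolerance = 1e-6)
  tr2 <- read_ppg_csv(file.path(dir, "ppg.csv"))
  expect_equal(tr2$voltage, tr$voltage, tolerance = 1e-6)
  fl2 <- read_flows_csv(file.path(dir, "flows.csv"))
  expect_equal(nrow(fl2), nrow(fl))
})
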