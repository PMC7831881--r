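test_that("modified Z score flags gross outliers only", {
  x <- c(1, 2, 3, 4, 100)
  mask <- modified_z_outliers(x)
  expect_identical(which(mask), 5L)
  # median 3, MAD 1 -> M = 0.6745 * 97
  expect_equal(attr(mask, "scores")[5], 0.6745 * 97)

  expect_warning(m2 <- modified_z_outliers(c(rep(5, 9), 5.1)), "MAD is zero")
  expect_false(any(is.na(m2)))

  expect_false(any(modified_z_outliers(c(-2, -1, 0, 1, 2))))
  expect_error(modified_z_outliers(c(1, 2)),
               class = "pauseflow_validation_error")
})

test_that("modified Z flags equal exhaustive formula evaluation", {
  set.seed(99)
  for (rep in 1:25) {
    x <- rnorm(50, sd = runif(1, 0.5, 3)) + c(rep(0, 47), runif(3, -20, 20))
    expect_identical(as.vector(modified_z_outliers(x)), brute_modified_z(x))
  }
})

test_that("elevated phases are excluded by duration and level", {
  prof <- make_activity_profile(default_params(12, "normocapnia"), 10,
                                seed = 31, elevated_rate = 0)
  keep <- exclude_elevated_phases(prof$mo2_true)
  expect_true(all(keep)) # regular cycling returns to baseline every cycle

  # 3 h plateau at 90% of range -> excluded
  x <- prof$mo2_true
  hi <- min(x) + 0.9 * diff(range(x))
  x2 <- c(x[1:120], rep(hi, 180), x[121:length(x)])
  keep2 <- exclude_elevated_phases(x2)
  expect_true(all(!keep2[160:260])) # plateau core masked out
  expect_true(all(keep2[1:60]))

  # a 1 h plateau is below the duration rule -> retained
  x3 <- c(x[1:120], rep(hi, 60), x[121:length(x)])
  expect_true(all(exclude_elevated_phases(x3)))

  expect_error(exclude_elevated_phases(rep(10, 300), min_duration_h = 6),
               class = "pauseflow_validation_error")
})

test_that("generator elevated episodes are caught by the exclusion mask", {
  p <- default_params(12, "normocapnia")
  # high episode rate so the 20 h record contains at least one
  prof <- make_activity_profile(p, 20, seed = 33, elevated_rate = 0.3)
  expect_gt(sum(prof$phase_label == "elevated"), 120)
  keep <- exclude_elevated_phases(prof$mo2_true)
  elevated <- prof$phase_label == "elevated"
  # most elevated samples must be masked out
  expect_gt(mean(!keep[elevated]), 0.8)
})

test_that("quartile occupancy counts range quarters exactly", {
  # square wave: 45 min low, 15 min high each hour
  x <- rep(c(rep(0, 45), rep(100, 15)), 10)
  occ <- quartile_occupancy(x, screen_outliers = FALSE)
  expect_equal(occ$frac_low, 0.75)
  expect_equal(occ$frac_high, 0.25)

  # affine invariance
  occ2 <- quartile_occupancy(3 * x + 17, screen_outliers = FALSE)
  expect_equal(occ2$frac_low, occ$frac_low)
  expect_equal(occ2$frac_high, occ$frac_high)

  # brute-force counting oracle on random fluctuating traces
  set.seed(5)
  for (rep in 1:10) {
    # smooth fluctuating trace: a random walk, as physiological series are
    y <- 25 + cumsum(rnorm(200))
    o <- quartile_occupancy(y, screen_outliers = FALSE)
    lo <- min(y) + 0.25 * diff(range(y))
    hi <- min(y) + 0.75 * diff(range(y))
    expect_equal(o$frac_low, sum(y < lo) / length(y))
    expect_equal(o$frac_high, sum(y > hi) / length(y))
  }

  expect_error(quartile_occupancy(rep(10, 100) + rnorm(100, 0, 1e-4) * 0,
                                  screen_outliers = FALSE),
               class = "pauseflow_validation_error")
  expect_error(quartile_occupancy(1:10), class = "pauseflow_validation_error")
})

test_that("12 C defaults occupy the lowest quartile ~40% of the time", {
  prof <- make_activity_profile(default_params(12, "normocapnia"), 20,
                                seed = 35, elevated_rate = 0)
  occ <- quartile_occupancy(prof$mo2_true, animal_id = "a1",
                            temperature = 12, co2_level = "normocapnia")
  expect_gt(occ$frac_low, 0.33)
  expect_lt(occ$frac_low, 0.47)
  expect_lte(occ$frac_low + occ$frac_high, 1)
})

test_that("low-quartile occupancy tracks the true pause fraction", {
  # pause level sits in the lowest quartile by construction, so occupancy
  # should recover the labelled pause share within 5 points at high SNR
  p <- default_params(12, "normocapnia", noise_sd = 0.5)
  prof <- make_activity_profile(p, 20, seed = 36, elevated_rate = 0)
  occ <- quartile_occupancy(prof$mo2_true)
  true_frac <- mean(prof$phase_label == "pause")
  expect_lte(abs(occ$frac_low - true_frac), 0.05)
})

test_that("hypercapnic warming doubles low-quartile occupancy", {
  frac <- function(co2, tt) {
    mean(sapply(1:3, function(s) {
      prof <- make_activity_profile(default_params(tt, co2), 20,
                                    seed = 100 + s, elevated_rate = 0)
      quartile_occupancy(prof$mo2_true)$frac_low
    }))
  }
  hyp <- mean(c(frac("hypercapnia", 18), frac("hypercapnia", 20)))
  nor <- mean(c(frac("normocapnia", 18), frac("normocapnia", 20)))
  expect_gt(hyp / nor, 1.5)
  expect_lt(hyp / nor, 2.5)
  expect_gte(hyp, 0.30) # hypercapnic band
  expect_lte(hyp, 0.50)
})

test_that("pulse counting matches constructed fixtures", {
  expect_equal(as.numeric(count_pulses(rep(5, 180))), 0)

  # four triangular pulses over two hours -> 2 per hour
  tri <- c(rep(0, 10), seq(0, 10, length.out = 5), seq(10, 0, length.out = 5),
           rep(0, 10))
  x <- rep(tri, 4)
  expect_equal(as.numeric(count_pulses(x)), 2)

  prof <- make_activity_profile(default_params(12, "normocapnia"), 10,
                                seed = 37, elevated_rate = 0)
  pph <- as.numeric(count_pulses(prof$mo2_true))
  expect_gte(pph, 1)
  expect_lte(pph, 3)

  expect_error(count_pulses(rep(5, 60)), class = "pauseflow_validation_error")
})
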