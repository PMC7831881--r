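#' Simulate vessel and ventilation flow-velocity records
#'
#' Emits per-timepoint, ROI-equivalent velocity records for the efferent
#' branchial veins of gills 6-8 (left and right), the arteria sternalis and
#' the excurrent ventilation channel (left and right). Branchial hemolymph
#' velocity is linearly coupled to the ventilatory water velocity of the
#' same side (`coupling_slope`) plus Gaussian noise, reproducing the
#' ventilation-perfusion correlation. Forward ventilation is encoded as
#' negative excurrent-channel velocity. During pause phases ventilation is
#' unilateral: one randomly chosen side carries all flow while the other is
#' exactly zero.
#'
#' @param profile an [make_activity_profile()] result.
#' @param coupling_slope branchial velocity per unit ventilation velocity
#'   (> 0).
#' @param coupling_noise SD of the Gaussian noise on branchial velocities
#'   (cm s^-1).
#' @param seed integer seed.
#' @return Data frame of class `vessel_flow_table` with columns `time_min`,
#'   `vessel` (branchial_6/7/8, arteria_sternalis, excurrent_channel),
#'   `side` (left/right/none) and `velocity_cm_s`.
#' @export
make_flow_series <- function(profile, coupling_slope = 0.6,
                             coupling_noise = 0.1, seed = NULL) {
  if (!inherits(profile, "activity_profile"))
    stop_validation("`profile` must be an activity_profile")
  if (coupling_slope <= 0) stop_validation("`coupling_slope` must be > 0")
  with_seed(seed, {
    n <- nrow(profile)
    pause <- profile$phase_label == "pause"
    # one ventilating side per contiguous pause episode
    runs <- rle(as.vector(pause))
    side_active <- rep("both", n)
    pos <- 1L
    for (r in seq_along(runs$lengths)) {
      len <- runs$lengths[r]
      if (runs$values[r])
        side_active[pos:(pos + len - 1L)] <-
          sample(c("left", "right"), 1L)
      pos <- pos + len
    }
    vent <- profile$vent_true
    vent_left <- ifelse(side_active == "both", vent / 2,
                        ifelse(side_active == "left", vent, 0))
    vent_right <- ifelse(side_active == "both", vent / 2,
                         ifelse(side_active == "right", vent, 0))

    branchial <- function(v_side) {
      lapply(c("branchial_6", "branchial_7", "branchial_8"), function(g) {
        coupling_slope * v_side +
          if (coupling_noise > 0) stats::rnorm(n, 0, coupling_noise) else 0
      })
    }
    bl <- branchial(vent_left)
    br <- branchial(vent_right)

    rows <- list()
    gn <- c("branchial_6", "branchial_7", "branchial_8")
    for (i in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        time_min = profile$time, vessel = gn[i], side = "left",
        velocity_cm_s = pmax(bl[[i]], 0))
      rows[[length(rows) + 1L]] <- data.frame(
        time_min = profile$time, vessel = gn[i], side = "right",
        velocity_cm_s = pmax(br[[i]], 0))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      time_min = profile$time, vessel = "arteria_sternalis", side = "none",
      velocity_cm_s = pmax(profile$perf_true +
                             if (coupling_noise > 0)
                               stats::rnorm(n, 0, coupling_noise) else 0, 0))
    # forward ventilation is negative at the excurrent channel
    rows[[length(rows) + 1L]] <- data.frame(
      time_min = profile$time, vessel = "excurrent_channel", side = "left",
      velocity_cm_s = -vent_left)
    rows[[length(rows) + 1L]] <- data.frame(
      time_min = profile$time, vessel = "excurrent_channel", side = "right",
      velocity_cm_s = -vent_right)

    out <- do.call(rbind, rows)
    class(out) <- c("vessel_flow_table", "data.frame")
    out
  })
}
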