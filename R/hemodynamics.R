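#' Aggregate branchial flow velocities per timepoint
#'
#' Per side, hemolymph velocities of gills 6-8 are averaged; the reported
#' branchial flow is the left mean plus the right mean. Ventilation is
#' reported as the summed magnitude of left and right excurrent-channel
#' velocities (the sign of the excurrent velocity encodes flow direction,
#' negative during forward ventilation). An absent side contributes 0 and
#' is flagged.
#'
#' @param table a `vessel_flow_table` data frame (columns `time_min`,
#'   `vessel`, `side`, `velocity_cm_s`).
#' @return Data frame with one row per timepoint: `time_min`,
#'   `branchial_left`, `branchial_right`, `branchial_sum`,
#'   `ventilation_sum`, `sternal`, `flag`.
#' @export
aggregate_branchial <- function(table) {
  need <- c("time_min", "vessel", "side", "velocity_cm_s")
  if (!all(need %in% names(table)))
    stop_validation("`table` must have columns ", paste(need, collapse = ", "))
  gills <- c("branchial_6", "branchial_7", "branchial_8")
  present <- intersect(gills, unique(table$vessel))
  flag <- NA_character_
  if (!length(present))
    stop_validation("no branchial vessels (gills 6-8) in the table")
  if (length(present) < 3L) {
    warning("missing branchial vessels: ",
            paste(setdiff(gills, present), collapse = ", "),
            "; averaging over available gills")
    flag <- "missing_gill"
  }

  times <- sort(unique(table$time_min))
  side_mean <- function(s) {
    sub <- table[table$vessel %in% present & table$side == s, ]
    if (!nrow(sub)) return(rep(0, length(times)))
    agg <- tapply(sub$velocity_cm_s, sub$time_min, mean)
    out <- rep(0, length(times))
    out[match(as.numeric(names(agg)), times)] <- as.numeric(agg)
    out
  }
  bl <- side_mean("left")
  br <- side_mean("right")

  vent_side <- function(s) {
    sub <- table[table$vessel == "excurrent_channel" & table$side == s, ]
    if (!nrow(sub)) return(rep(0, length(times)))
    agg <- tapply(abs(sub$velocity_cm_s), sub$time_min, mean)
    out <- rep(0, length(times))
    out[match(as.numeric(names(agg)), times)] <- as.numeric(agg)
    out
  }
  vent <- vent_side("left") + vent_side("right")

  stern <- {
    sub <- table[table$vessel == "arteria_sternalis", ]
    if (nrow(sub)) {
      agg <- tapply(sub$velocity_cm_s, sub$time_min, mean)
      out <- rep(NA_real_, length(times))
      out[match(as.numeric(names(agg)), times)] <- as.numeric(agg)
      out
    } else rep(NA_real_, length(times))
  }

  data.frame(time_min = times,
             branchial_left = bl,
             branchial_right = br,
             branchial_sum = bl + br,
             ventilation_sum = vent,
             sternal = stern,
             flag = flag,
             stringsAsFactors = FALSE)
}

#' Ventilation-perfusion linear correlation
#'
#' Pearson correlation and least-squares regression of branchial hemolymph
#' flow on ventilatory water flow, as used to assess the coupling of the
#' two systems.
#'
#' @param vent ventilatory water-flow velocities.
#' @param perf branchial hemolymph-flow velocities, paired with `vent`.
#' @return list with `r`, `r_squared`, `slope`, `intercept`, `p` (two-sided
#'   test of r != 0) and `n`.
#' @export
vent_perf_correlation <- function(vent, perf) {
  ok <- stats::complete.cases(vent, perf)
  vent <- vent[ok]; perf <- perf[ok]
  if (length(vent) < 3)
    stop_validation("need at least 3 paired observations")
  if (stats::sd(vent) == 0 || stats::sd(perf) == 0)
    stop_validation("correlation undefined: zero variance in a series")
  ct <- stats::cor.test(vent, perf)
  fit <- stats::lm(perf ~ vent)
  list(r = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = ct$p.value,
       n = length(vent))
}

#' Cardiac contractility from ventricular diameters
#'
#' Contractility is the change in lateral ventricular diameter (measured
#' between the two in-plane ostia) between end-diastole and end-systole,
#' reported in mm and as percent of the end-diastolic diameter.
#'
#' @param d_diastole end-diastolic lateral diameter in mm (> 0).
#' @param d_systole end-systolic lateral diameter in mm (<= `d_diastole`).
#' @return Data frame with `d_diastole`, `d_systole`, `delta` (mm) and
#'   `percent_of_diastolic`.
#' @examples
#' contractility(21.5, 18.7) # delta 2.8 mm, 13% of diastolic
#' @export
contractility <- function(d_diastole, d_systole) {
  if (any(d_diastole <= 0)) stop_validation("`d_diastole` must be > 0")
  if (any(d_systole < 0)) stop_validation("`d_systole` must be >= 0")
  if (any(d_systole > d_diastole))
    stop_validation("`d_systole` exceeds `d_diastole`")
  delta <- d_diastole - d_systole
  data.frame(d_diastole = d_diastole,
             d_systole = d_systole,
             delta = delta,
             percent_of_diastolic = 100 * delta / d_diastole)
}
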