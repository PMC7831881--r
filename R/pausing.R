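#' Robust outlier screen by modified Z score
#'
#' Iglewicz-Hoaglin modified Z score,
#' `M_i = 0.6745 (x_i - median) / MAD`; points with `|M_i| >= threshold`
#' (default 3.5) are flagged. If the MAD is zero the mean absolute
#' deviation from the median is used instead, with a warning.
#'
#' @param values numeric vector (n >= 3).
#' @param threshold flagging threshold on `|M|` (default 3.5).
#' @return logical vector, `TRUE` for outliers; the scores are attached as
#'   `attr(, "scores")`.
#' @examples
#' modified_z_outliers(c(1, 2, 3, 4, 100)) # flags only 100
#' @export
modified_z_outliers <- function(values, threshold = 3.5) {
  values <- as.numeric(values)
  if (sum(!is.na(values)) < 3)
    stop_validation("need at least 3 non-missing values")
  med <- stats::median(values, na.rm = TRUE)
  mad0 <- stats::median(abs(values - med), na.rm = TRUE)
  if (mad0 > 0) {
    m <- 0.6745 * (values - med) / mad0
  } else {
    warning("MAD is zero; falling back to the mean absolute deviation")
    meanad <- mean(abs(values - med), na.rm = TRUE)
    if (meanad == 0) {
      m <- rep(0, length(values))
    } else {
      m <- 0.7979 * (values - med) / meanad
    }
  }
  out <- !is.na(m) & abs(m) >= threshold
  attr(out, "scores") <- m
  out
}

#' Mask out phases of continuously elevated activity
#'
#' Spontaneous episodes during which metabolic rate stays high for hours are
#' excluded before pausing statistics: a timepoint is flagged as elevated
#' when the rolling minimum of the trace over `window` minutes stays above
#' `range_min + frac * range`, and contiguous flagged spans of at least
#' `min_duration_h` hours are excluded. The remainder is the
#' "fluctuating activity" mask.
#'
#' @param mo2 metabolic-rate series (1 sample per `dt_min` minutes).
#' @param window rolling-minimum window in minutes (default 60).
#' @param frac range fraction the rolling minimum must exceed (default 0.5).
#' @param min_duration_h minimum excluded-span duration in hours (default 2).
#' @param dt_min sampling interval in minutes.
#' @return logical inclusion mask (`TRUE` = keep).
#' @export
exclude_elevated_phases <- function(mo2, window = 60, frac = 0.5,
                                    min_duration_h = 2, dt_min = 1) {
  mo2 <- as.numeric(mo2)
  n <- length(mo2)
  if (n * dt_min <= min_duration_h * 60)
    stop_validation("trace shorter than `min_duration_h`")
  ok <- !is.na(mo2)
  rng <- range(mo2[ok])
  cut <- rng[1] + frac * (rng[2] - rng[1])
  w <- max(round(window / dt_min), 1L)
  rollmin <- .rolling_min(ifelse(ok, mo2, Inf), w)
  high <- rollmin > cut
  # the rolling minimum erodes an episode by half a window on each side;
  # dilate the detected core back to the episode's true extent before
  # applying the duration rule
  half <- w %/% 2
  if (any(high) && half > 0) {
    idx <- which(high)
    lo <- pmax(idx - half, 1L)
    hi <- pmin(idx + half, n)
    dil <- logical(n)
    for (j in seq_along(idx)) dil[lo[j]:hi[j]] <- TRUE
    high <- dil
  }
  # contiguous high spans >= min_duration
  runs <- rle(as.vector(high))
  keep <- rep(TRUE, n)
  pos <- 1L
  min_len <- min_duration_h * 60 / dt_min
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    if (runs$values[r] && len >= min_len)
      keep[pos:(pos + len - 1L)] <- FALSE
    pos <- pos + len
  }
  if (!any(keep))
    stop_validation("all samples excluded as elevated activity")
  keep
}

# centred rolling minimum with shrinking windows at the edges
#' @keywords internal
.rolling_min <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  vapply(seq_len(n), function(i) {
    min(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Quartile occupancy of the metabolic-rate range
#'
#' For one combination of animal, temperature and CO2 level, the total
#' range of the (outlier-screened) metabolic-rate values is divided into
#' quarters, and the fractions of time spent in the lowest and highest 25%
#' of the range are reported. Pauses place the animal in the lowest
#' quarter, metabolic pulses in the highest, so these fractions quantify
#' pausing behaviour.
#'
#' @param mo2 metabolic-rate samples of the analysis window (already
#'   restricted to fluctuating activity; see [exclude_elevated_phases()]).
#' @param animal_id,temperature,co2_level group identifiers carried into
#'   the result.
#' @param screen_outliers apply [modified_z_outliers()] before computing the
#'   range (default `TRUE`).
#' @param min_samples minimum number of retained samples (default 60).
#' @return Data frame of class `occupancy_result` with columns `animal_id`,
#'   `temperature`, `co2_level`, `range_min`, `range_max`, `frac_low`,
#'   `frac_high`, `n_samples`.
#' @export
quartile_occupancy <- function(mo2, animal_id = NA, temperature = NA,
                               co2_level = NA, screen_outliers = TRUE,
                               min_samples = 60) {
  mo2 <- as.numeric(mo2)
  mo2 <- mo2[!is.na(mo2)]
  if (screen_outliers && length(mo2) >= 3)
    mo2 <- mo2[!modified_z_outliers(mo2)]
  if (length(mo2) < min_samples)
    stop_validation("fewer than ", min_samples, " retained samples")
  rng <- range(mo2)
  span <- rng[2] - rng[1]
  # degenerate, non-fluctuating records mirror the excluded
  # constant-performance animals
  tol <- 10 * stats::median(abs(diff(mo2)))
  if (span <= tol || span <= 0)
    stop_validation("degenerate metabolic range (non-fluctuating record)")
  q25 <- rng[1] + 0.25 * span
  q75 <- rng[1] + 0.75 * span
  out <- data.frame(animal_id = animal_id,
                    temperature = temperature,
                    co2_level = co2_level,
                    range_min = rng[1],
                    range_max = rng[2],
                    frac_low = mean(mo2 < q25),
                    frac_high = mean(mo2 > q75),
                    n_samples = length(mo2),
                    stringsAsFactors = FALSE)
  class(out) <- c("occupancy_result", "data.frame")
  out
}

#' Count metabolic pulses per hour
#'
#' Local maxima with prominence of at least `prominence_frac` of the total
#' range, separated by at least `min_separation` minutes, divided by the
#' record duration in hours.
#'
#' @param mo2 metabolic-rate series.
#' @param dt_min sampling interval in minutes.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   range (default 0.5).
#' @param min_separation minimum peak separation in minutes (default 10).
#' @return pulses per hour; the peak sample indices are attached as
#'   `attr(, "peaks")`.
#' @export
count_pulses <- function(mo2, dt_min = 1, prominence_frac = 0.5,
                         min_separation = 10) {
  mo2 <- as.numeric(mo2)
  n <- length(mo2)
  hours <- n * dt_min / 60
  if (hours < 2) stop_validation("need at least 2 h of data")
  rng <- range(mo2, na.rm = TRUE)
  span <- rng[2] - rng[1]
  if (span == 0) {
    out <- 0
    attr(out, "peaks") <- integer(0)
    return(out)
  }
  thr <- rng[1] + prominence_frac * span
  # candidate maxima above the prominence threshold
  cand <- which(c(FALSE, mo2[2:(n - 1)] > mo2[1:(n - 2)] &
                    mo2[2:(n - 1)] >= mo2[3:n], FALSE) & mo2 > thr)
  peaks <- integer(0)
  sep <- min_separation / dt_min
  last <- -Inf
  for (i in cand) {
    if (i - last >= sep) {
      peaks <- c(peaks, i)
      last <- i
    } else if (mo2[i] > mo2[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i # keep the taller of close peaks
      last <- i
    }
  }
  # require the signal to drop below threshold between retained peaks
  # (prominence relative to the range floor)
  if (length(peaks) > 1) {
    keep <- peaks[1]
    for (i in peaks[-1]) {
      lo <- min(mo2[(keep[length(keep)]):i], na.rm = TRUE)
      if (lo <= thr) keep <- c(keep, i)
    }
    peaks <- keep
  }
  out <- length(peaks) / hours
  attr(out, "peaks") <- peaks
  out
}
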