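# CSV/JSON interchange. All tabular output is RFC-4180 CSV with a header
# row; units are encoded in the column names.

#' Write a set of synthetic recordings to disk
#'
#' Writes `optode.csv` (time_min, inflow_torr, outflow_torr), `ppg.csv`
#' (time_s, voltage_V), `flows.csv` (time_min, vessel, side, velocity_cm_s),
#' `truth.csv` (the activity profile) and a `params.json` sidecar with the
#' generating parameters and seed.
#'
#' @param dir output directory (created if missing).
#' @param profile,optode,ppg,flows generator outputs; any may be `NULL` to
#'   skip the corresponding file.
#' @param seed the seed used, recorded in the sidecar.
#' @return invisibly, the paths written.
#' @export
write_recordings <- function(dir, profile = NULL, optode = NULL, ppg = NULL,
                             flows = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(profile)) {
    p <- file.path(dir, "truth.csv")
    utils::write.csv(as.data.frame(profile), p, row.names = FALSE)
    paths <- c(paths, p)
    pj <- attr(profile, "params")
    if (!is.null(pj)) {
      sidecar <- file.path(dir, "params.json")
      jsonlite::write_json(c(unclass(pj), list(seed = seed)), sidecar,
                           auto_unbox = TRUE, digits = NA)
      paths <- c(paths, sidecar)
    }
  }
  if (!is.null(optode)) {
    p <- file.path(dir, "optode.csv")
    utils::write.csv(as.data.frame(optode), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(ppg)) {
    p <- file.path(dir, "ppg.csv")
    d <- data.frame(time_s = ppg$time_s, voltage_V = ppg$voltage)
    utils::write.csv(d, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(flows)) {
    p <- file.path(dir, "flows.csv")
    utils::write.csv(as.data.frame(flows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an optode CSV
#'
#' @param path CSV with columns `time_min`, `inflow_torr`, `outflow_torr`.
#' @param temperature,salinity water conditions attached as attributes
#'   (used for the solubility coefficient).
#' @return an `optode_pair` data frame.
#' @export
read_optode_csv <- function(path, temperature = 12, salinity = 33) {
  d <- utils::read.csv(path)
  need <- c("time_min", "inflow_torr", "outflow_torr")
  if (!all(need %in% names(d)))
    stop_validation(path, " must have columns ", paste(need, collapse = ", "))
  if (is.unsorted(d$time_min, strictly = TRUE))
    stop_validation("time_min must be strictly increasing")
  attr(d, "temperature") <- temperature
  attr(d, "salinity") <- salinity
  class(d) <- c("optode_pair", "data.frame")
  d
}

#' Read a PPG CSV
#'
#' @param path CSV with columns `time_s`, `voltage_V` (or `voltage`).
#' @return a `ppg_trace` data frame.
#' @export
read_ppg_csv <- function(path) {
  d <- utils::read.csv(path)
  vcol <- intersect(c("voltage_V", "voltage"), names(d))
  if (!("time_s" %in% names(d)) || !length(vcol))
    stop_validation(path, " must have columns time_s and voltage_V")
  ppg_trace(d$time_s, d[[vcol[1]]])
}

#' Read a vessel flow CSV
#'
#' @param path CSV with columns `time_min`, `vessel`, `side`,
#'   `velocity_cm_s`.
#' @return a `vessel_flow_table` data frame.
#' @export
read_flows_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "vessel", "side", "velocity_cm_s")
  if (!all(need %in% names(d)))
    stop_validation(path, " must have columns ", paste(need, collapse = ", "))
  class(d) <- c("vessel_flow_table", "data.frame")
  d
}
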