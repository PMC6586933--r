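#' Construct a stimulus schedule
#'
#' A schedule is an ordered table of perfusion epochs: for each application,
#' the compound, its concentration, the valve-opening time and the application
#' duration, plus the epoch's role in the experiment (viability control such
#' as ATP, test stimulus, vehicle control such as Ringer's solution, or a
#' calibration epoch such as fluorescein).
#'
#' @param compound Character vector of compound names (e.g. `"ATP"`,
#'   `"denatonium"`, `"Ringer"`).
#' @param concentration_mM Numeric vector of concentrations in mM (express
#'   micromolar as mM, e.g. 30 uM ATP is 0.03). Vehicle epochs use 0.
#' @param valve_open_s Numeric vector, valve-opening times in seconds from
#'   the start of the recording.
#' @param duration_s Numeric vector, application durations in seconds.
#' @param role Character vector, one of `"viability_control"`, `"test"`,
#'   `"vehicle_control"`, `"calibration"`.
#' @param epoch_id Integer ids; defaults to `seq_along(compound)`.
#'
#' @return A `data.frame` with class `ca_schedule`, sorted by `valve_open_s`.
#' @examples
#' stim_schedule(
#'   compound = c("Ringer", "ATP", "denatonium"),
#'   concentration_mM = c(0, 0.03, 5),
#'   valve_open_s = c(30, 120, 210),
#'   duration_s = 10,
#'   role = c("vehicle_control", "viability_control", "test")
#' )
#' @export
stim_schedule <- function(compound, concentration_mM, valve_open_s,
                          duration_s, role = "test",
                          epoch_id = seq_along(compound)) {
  sched <- data.frame(
    epoch_id = as.integer(epoch_id),
    compound = as.character(compound),
    concentration_mM = as.numeric(concentration_mM),
    valve_open_s = as.numeric(valve_open_s),
    duration_s = as.numeric(duration_s),
    role = as.character(role),
    stringsAsFactors = FALSE
  )
  sched <- sched[order(sched$valve_open_s), , drop = FALSE]
  rownames(sched) <- NULL
  validate_schedule(sched)
  class(sched) <- c("ca_schedule", "data.frame")
  sched
}

validate_schedule <- function(sched) {
  req <- c("epoch_id", "compound", "concentration_mM", "valve_open_s",
           "duration_s", "role")
  miss <- setdiff(req, names(sched))
  if (length(miss))
    stop("schedule is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sched$epoch_id))
    stop("schedule field 'epoch_id' contains duplicates")
  if (any(!is.finite(sched$valve_open_s)))
    stop("schedule field 'valve_open_s' must be finite")
  if (any(sched$concentration_mM < 0))
    stop("schedule field 'concentration_mM' must be >= 0")
  if (any(sched$compound == "Ringer" & sched$concentration_mM != 0))
    stop("schedule: Ringer epochs must have concentration 0")
  roles <- c("viability_control", "test", "vehicle_control", "calibration")
  if (any(!sched$role %in% roles))
    stop("schedule field 'role' must be one of: ", paste(roles, collapse = ", "))
  o <- order(sched$valve_open_s)
  ends <- sched$valve_open_s[o] + sched$duration_s[o]
  if (any(utils::head(ends, -1) > sched$valve_open_s[o][-1]))
    stop("schedule epochs overlap after sorting by 'valve_open_s'")
  invisible(sched)
}

#' Construct a raw fluorescence recording
#'
#' Bundles a common time base, a cells-by-time matrix of raw fluorescence
#' (arbitrary units), cell identifiers, the stimulus schedule and free-form
#' metadata into a validated `ca_recording` object — the unit on which the
#' whole pipeline operates (one slice experiment).
#'
#' @param time Numeric vector of acquisition times in seconds, strictly
#'   increasing and uniform within a 1 percent jitter tolerance.
#' @param traces Numeric matrix, one row per cell, one column per time point.
#' @param cell_ids Unique cell labels; default `cell_1 ... cell_n`.
#' @param schedule A [stim_schedule()]; all epochs must lie inside the time
#'   range of the recording.
#' @param metadata Named list of free-form metadata (slice id, sampling rate).
#'
#' @return An object of class `ca_recording` with elements `time`, `traces`,
#'   `cell_ids`, `schedule`, `metadata`.
#' @export
ca_recording <- function(time, traces, cell_ids = NULL, schedule = NULL,
                         metadata = list()) {
  traces <- as.matrix(traces)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(traces)))
  rec <- structure(
    list(time = as.numeric(time), traces = traces,
         cell_ids = as.character(cell_ids),
         schedule = schedule, metadata = metadata),
    class = "ca_recording"
  )
  validate_recording(rec)
  rownames(rec$traces) <- rec$cell_ids
  rec
}

validate_recording <- function(rec) {
  time <- rec$time
  if (anyNA(time)) stop("recording field 'time' contains NA")
  if (length(time) < 2) stop("recording field 'time' needs >= 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("recording field 'time' must be strictly increasing")
  if (max(dt) > 1.01 * median(dt) + 1e-12 || min(dt) < 0.99 * median(dt) - 1e-12)
    stop("recording field 'time' is non-uniform beyond 1% jitter tolerance")
  if (ncol(rec$traces) != length(time))
    stop("recording field 'traces' must have one column per time point")
  if (nrow(rec$traces) != length(rec$cell_ids))
    stop("recording field 'cell_ids' must have one entry per trace row")
  if (anyDuplicated(rec$cell_ids))
    stop("recording field 'cell_ids' contains duplicates")
  nna <- rowMeans(is.na(rec$traces))
  if (any(nna > 0.05))
    stop("recording field 'traces': cell(s) ",
         paste(rec$cell_ids[nna > 0.05], collapse = ", "),
         " exceed 5% NaN/NA samples")
  if (!is.null(rec$schedule)) {
    validate_schedule(rec$schedule)
    if (any(rec$schedule$valve_open_s < time[1]) ||
        any(rec$schedule$valve_open_s + rec$schedule$duration_s > time[length(time)]))
      stop("schedule epochs extend outside the recording time range")
  }
  invisible(rec)
}

#' @export
print.ca_recording <- function(x, ...) {
  cat(sprintf("<ca_recording> %d cells x %d samples, %.1f-%.1f s (dt = %.3g s)\n",
              nrow(x$traces), length(x$time), x$time[1],
              x$time[length(x$time)], median(diff(x$time))))
  if (!is.null(x$schedule)) {
    cat(sprintf("  schedule: %d epochs (%s)\n", nrow(x$schedule),
                paste(unique(x$schedule$compound), collapse = ", ")))
  } else cat("  schedule: none\n")
  invisible(x)
}

#' @export
print.ca_normalized <- function(x, ...) {
  cat(sprintf("<ca_normalized> %d cells x %d samples, bleach-corrected: %s\n",
              nrow(x$dff), length(x$time), x$corrected))
  invisible(x)
}

# sampling interval (s), robust to jitter
rec_dt <- function(rec) median(diff(rec$time))
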