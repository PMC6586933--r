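#' Read a trace table into a recording
#'
#' Reads per-ROI fluorescence time series from a CSV file. Two dialects are
#' supported: wide (a `time_s` column plus one column per cell) and long
#' (columns `time_s`, `cell_id`, `F`). Time is in seconds; fluorescence in
#' arbitrary units. If a schedule sidecar `<path basename>_schedule.csv`
#' exists next to the file (or `schedule_path` is given) it is attached.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @param schedule_path Optional explicit schedule CSV path.
#' @param time_col Name of the time column (default `"time_s"`; `"t"` and
#'   `"time"` are also recognized).
#' @return A validated [ca_recording()].
#' @export
read_traces <- function(path, dialect = c("wide", "long"),
                        schedule_path = NULL, time_col = "time_s") {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE)
  tc <- intersect(c(time_col, "time_s", "time", "t"), names(df))[1]
  if (is.na(tc)) stop("parse error in ", path, ": no time column (tried '",
                      time_col, "', 'time_s', 'time', 't')")
  if (dialect == "wide") {
    if (anyDuplicated(df[[tc]]))
      stop("parse error in ", path, ": duplicate time stamps in '", tc, "'")
    if (is.unsorted(df[[tc]], strictly = TRUE))
      stop("parse error in ", path, ": time column '", tc,
           "' is not strictly increasing")
    cells <- setdiff(names(df), tc)
    if (!length(cells)) stop("parse error in ", path, ": no trace columns")
    traces <- t(as.matrix(df[cells]))
    time <- df[[tc]]
    ids <- cells
  } else {
    need <- c(tc, "cell_id", "F")
    if (!all(need %in% names(df)))
      stop("parse error in ", path, ": long dialect needs columns ",
           paste(need, collapse = ", "))
    time <- sort(unique(df[[tc]]))
    ids <- unique(df$cell_id)
    traces <- matrix(NA_real_, length(ids), length(time),
                     dimnames = list(ids, NULL))
    ti <- match(df[[tc]], time)
    ci <- match(df$cell_id, ids)
    traces[cbind(ci, ti)] <- df$F
  }
  sched <- NULL
  if (is.null(schedule_path)) {
    cand <- paste0(sub("\\.[^.]*$", "", path), "_schedule.csv")
    if (file.exists(cand)) schedule_path <- cand
  }
  if (!is.null(schedule_path)) sched <- read_schedule(schedule_path)
  ca_recording(time, traces, ids, sched,
               metadata = list(source = path))
}

#' Write a recording's traces as a wide CSV (plus schedule sidecar)
#'
#' @param recording A [ca_recording()].
#' @param path Output CSV path; the schedule, if present, is written to
#'   `<path basename>_schedule.csv`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(recording, path) {
  df <- data.frame(time_s = recording$time, check.names = FALSE)
  tr <- t(recording$traces)
  colnames(tr) <- recording$cell_ids
  df <- cbind(df, as.data.frame(tr, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(recording$schedule))
    write_schedule(recording$schedule,
                   paste0(sub("\\.[^.]*$", "", path), "_schedule.csv"))
  invisible(path)
}

#' Read / write a stimulus schedule CSV
#'
#' Columns: `epoch_id, compound, concentration_mM, valve_open_s, duration_s,
#' role`.
#'
#' @param path CSV path.
#' @return [read_schedule()]: a validated schedule; [write_schedule()]:
#'   `path`, invisibly.
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stim_schedule(compound = df$compound,
                concentration_mM = df$concentration_mM,
                valve_open_s = df$valve_open_s,
                duration_s = df$duration_s,
                role = df$role,
                epoch_id = df$epoch_id)
}

#' @rdname read_schedule
#' @param schedule A [stim_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Extract per-ROI mean traces from an image stack
#'
#' For every positive label in the mask, averages the stack's pixel values
#' over that label's pixels, frame by frame, yielding one trace per ROI — the
#' standard ROI-mean measurement around a single cell.
#'
#' @param stack Numeric array `h x w x frames`.
#' @param mask Integer matrix `h x w`; 0 = background, positive integers are
#'   ROI labels (need not be consecutive). Label order defines cell order.
#' @param schedule Optional [stim_schedule()] to attach.
#' @param time Optional time axis in seconds; defaults to frame index at
#'   `sampling_rate_hz`.
#' @param sampling_rate_hz Sampling rate used when `time` is missing.
#' @return A [ca_recording()] with cell ids `roi_<label>`.
#' @export
extract_rois <- function(stack, mask, schedule = NULL, time = NULL,
                         sampling_rate_hz = 2) {
  d <- dim(stack)
  if (length(d) != 3 || !all(d[1:2] == dim(mask)))
    stop("dimension error: stack frames (", d[1], "x", d[2],
         ") do not match mask (", paste(dim(mask), collapse = "x"), ")")
  if (any(mask < 0) || any(mask != round(mask)))
    stop("mask labels must be non-negative integers")
  labels <- sort(unique(mask[mask > 0]))
  nt <- d[3]
  if (is.null(time)) time <- (seq_len(nt) - 1) / sampling_rate_hz
  if (!length(labels)) {
    warning("empty mask: no positive labels, returning no cells")
    traces <- matrix(numeric(0), nrow = 0, ncol = nt)
    npx <- integer(0)
  } else {
    flat <- matrix(stack, nrow = d[1] * d[2], ncol = nt)
    keep <- as.vector(mask) > 0
    sums <- rowsum(flat[keep, , drop = FALSE], group = as.vector(mask)[keep])
    npx <- as.vector(table(mask[mask > 0]))
    traces <- sums / npx
  }
  ids <- if (length(labels)) paste0("roi_", labels) else character(0)
  ca_recording(time, traces, cell_ids = ids,
               schedule = schedule,
               metadata = list(roi_pixels = stats::setNames(npx, labels)))
}

#' Write / read an image stack and ROI mask as TIFF
#'
#' The stack is written as a multi-page 32-bit float TIFF (values rescaled to
#' \[0, 1\] by `scale`, recorded so the reader can invert it); the mask as a
#' single-page 16-bit label TIFF.
#'
#' @param stack Numeric array `h x w x frames`.
#' @param path Output TIFF path.
#' @param scale Value mapped to 1.0 in the file; default `max(stack)`.
#' @return The path, invisibly (writers) or the array/matrix (readers).
#' @export
write_stack <- function(stack, path, scale = max(stack)) {
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) stack[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  attr(path, "scale") <- scale
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]]
  stack * scale
}

#' @rdname write_stack
#' @param mask Integer label matrix (0 = background).
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535) stop("mask labels exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write / read response calls
#'
#' Long-format CSV with one row per (cell, epoch): `cell_id, epoch_id,
#' compound, responsive, peak_dff, peak_time_s, onset_time_s, onset_delay_s,
#' suprathreshold_duration_s, threshold, exclusion_reason`.
#'
#' @param calls A calls data frame from [call_recording()].
#' @param path CSV path.
#' @return `path` invisibly; [read_calls()] returns the calls data frame.
#' @export
write_calls <- function(calls, path) {
  cols <- call_columns()
  if (nrow(calls) == 0) {
    empty <- as.data.frame(stats::setNames(
      lapply(cols, function(x) logical(0)), cols))
    utils::write.csv(empty, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  utils::write.csv(calls[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(call_columns(), names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing call column(s): ",
         paste(miss, collapse = ", "))
  df$responsive <- as.logical(df$responsive)
  df
}

call_columns <- function() {
  c("cell_id", "epoch_id", "compound", "responsive", "peak_dff",
    "peak_time_s", "onset_time_s", "onset_delay_s",
    "suprathreshold_duration_s", "threshold", "exclusion_reason")
}

#' Write / read the generator's ground truth
#'
#' Long-format CSV, one row per generated transient joined with the cell's
#' class: `cell_id, class, epoch_id, true_onset_s, true_peak_dff` (cells
#' without events appear once with NA event fields).
#'
#' @param truth A `ca_truth` object from [generate_recording()].
#' @param path CSV path.
#' @export
write_truth <- function(truth, path) {
  ev <- merge(truth$cells[, c("cell_id", "class")], truth$events,
              by = "cell_id", all.x = TRUE)
  ev <- ev[order(ev$cell_id, ev$epoch_id), ]
  utils::write.csv(
    ev[, c("cell_id", "class", "epoch_id", "true_onset_s", "true_peak_dff")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
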