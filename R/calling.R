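#' Response-calling parameters
#'
#' The responsiveness rule: a cell responds to an epoch if its dF/F0 stays
#' strictly above the prestimulus mean plus `k_sd` standard deviations for at
#' least `min_duration_s`, in a run starting within `search_window_s` of
#' valve opening; cells responding to the vehicle (Ringer) application or
#' showing spontaneous activity are excluded from analysis.
#'
#' @param prestim_window_s Baseline window length before each valve opening
#'   (seconds, default 15).
#' @param k_sd Threshold multiplier on the baseline SD (default 3).
#' @param min_duration_s Minimum supra-threshold duration (seconds, default 5).
#' @param search_window_s Window after valve opening within which a response
#'   may begin (seconds, default 60).
#' @param ringer_policy,spontaneous_policy Enable the vehicle-response and
#'   spontaneous-activity exclusions (default both `TRUE`).
#' @param min_spont_samples Minimum run length (samples) for the spontaneous
#'   detector (default 3).
#' @return A list of class `call_params`.
#' @export
call_params <- function(prestim_window_s = 15, k_sd = 3, min_duration_s = 5,
                        search_window_s = 60, ringer_policy = TRUE,
                        spontaneous_policy = TRUE, min_spont_samples = 3L) {
  stopifnot(prestim_window_s > 0, k_sd > 0, min_duration_s > 0,
            search_window_s >= min_duration_s)
  structure(list(prestim_window_s = prestim_window_s, k_sd = k_sd,
                 min_duration_s = min_duration_s,
                 search_window_s = search_window_s,
                 ringer_policy = ringer_policy,
                 spontaneous_policy = spontaneous_policy,
                 min_spont_samples = as.integer(min_spont_samples)),
            class = "call_params")
}

# Latest clean prestimulus window ending at or before this epoch's valve
# opening: windows overlapping an earlier epoch's search window are shifted
# earlier to the nearest clean segment. Returns a logical sample index, or
# NULL when no window with >= 5 samples exists.
prestim_index <- function(time, schedule, epoch_id, params) {
  ep <- schedule[schedule$epoch_id == epoch_id, ]
  valve <- ep$valve_open_s
  others <- schedule[schedule$valve_open_s < valve, , drop = FALSE]
  forb <- cbind(others$valve_open_s,
                others$valve_open_s + params$search_window_s)
  w <- params$prestim_window_s
  ends <- sort(unique(c(valve, forb[forb[, 1] < valve, 1])), decreasing = TRUE)
  for (e in ends) {
    s <- e - w
    if (s < time[1] - 1e-9) next
    clean <- !nrow(forb) ||
      all(forb[, 2] <= s + 1e-9 | forb[, 1] >= e - 1e-9)
    if (!clean) next
    idx <- time >= s & time < e
    if (sum(idx) >= 5) return(idx)
  }
  NULL
}

#' Prestimulus baseline statistics and threshold for one epoch
#'
#' Mean and sample SD (n-1 denominator) of dF/F0 over the prestimulus
#' window, and the response threshold `mean + k_sd * sd`.
#'
#' @param dff Numeric dF/F0 trace for one cell.
#' @param time Time axis (seconds).
#' @param schedule The recording's [stim_schedule()].
#' @param epoch_id Epoch to threshold.
#' @param params [call_params()].
#' @return List `mean`, `sd`, `threshold`, `window` (logical sample index),
#'   or `NULL` when no clean baseline window of >= 5 samples exists.
#' @export
epoch_threshold <- function(dff, time, schedule, epoch_id, params = call_params()) {
  idx <- prestim_index(time, schedule, epoch_id, params)
  if (is.null(idx)) return(NULL)
  m <- mean(dff[idx], na.rm = TRUE)
  s <- stats::sd(dff[idx], na.rm = TRUE)
  list(mean = m, sd = s, threshold = m + params$k_sd * s, window = idx)
}

#' Classify one cell's response to one epoch
#'
#' Responsive iff some run of consecutive samples strictly above the
#' threshold, starting within the search window after valve opening, spans
#' at least `min_duration_s` (each sample counts one sampling period).
#' The onset time is the threshold-crossing time, linearly interpolated
#' between the last sub-threshold sample and the first sample of the
#' qualifying run; the peak is the maximum dF/F0 over the search window.
#'
#' @inheritParams epoch_threshold
#' @return One-row data frame (see [write_calls()] for columns).
#' @export
call_epoch <- function(dff, time, schedule, epoch_id, params = call_params()) {
  ep <- schedule[schedule$epoch_id == epoch_id, ]
  valve <- ep$valve_open_s
  dt <- median(diff(time))
  out <- data.frame(cell_id = NA_character_, epoch_id = epoch_id,
                    compound = ep$compound, responsive = FALSE,
                    peak_dff = NA_real_, peak_time_s = NA_real_,
                    onset_time_s = NA_real_, onset_delay_s = NA_real_,
                    suprathreshold_duration_s = NA_real_,
                    threshold = NA_real_, exclusion_reason = "none",
                    stringsAsFactors = FALSE)

  thr <- epoch_threshold(dff, time, schedule, epoch_id, params)
  if (is.null(thr)) {
    out$exclusion_reason <- "insufficient_baseline"
    return(out)
  }
  out$threshold <- thr$threshold

  t_end <- time[length(time)]
  if (t_end < valve + params$min_duration_s) {
    warning("epoch ", epoch_id, " window truncated by recording end")
    out$exclusion_reason <- "insufficient_baseline"
    return(out)
  }

  search <- time >= valve & time <= valve + params$search_window_s
  out$peak_dff <- max(dff[search], na.rm = TRUE)
  out$peak_time_s <- time[search][which.max(dff[search])]

  # runs of consecutive supra-threshold samples from valve opening onward
  post <- which(time >= valve)
  above <- dff[post] > thr$threshold
  above[is.na(above)] <- FALSE
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  ok <- r$values
  starts_in <- time[post[run_start]] <= valve + params$search_window_s
  span <- r$lengths * dt
  qual <- ok & starts_in & span >= params$min_duration_s - 1e-9
  if (any(qual)) {
    q1 <- which(qual)[1]
    i0 <- post[run_start[q1]]
    out$responsive <- TRUE
    out$onset_time_s <- crossing_time(dff, time, i0, thr$threshold)
    out$onset_delay_s <- out$onset_time_s - valve
    out$suprathreshold_duration_s <- max(span[qual])
  }
  out
}

# interpolated threshold-crossing time at the start of a supra-threshold run
crossing_time <- function(dff, time, i0, threshold) {
  if (i0 == 1 || is.na(dff[i0 - 1]) || dff[i0 - 1] > threshold)
    return(time[i0])
  y0 <- dff[i0 - 1]; y1 <- dff[i0]
  if (y1 == y0) return(time[i0])
  time[i0 - 1] + (threshold - y0) / (y1 - y0) * (time[i0] - time[i0 - 1])
}

#' Detect spontaneous activity outside stimulus windows
#'
#' Applies the same mean + `k_sd` * SD rule with a rolling baseline (the
#' preceding `prestim_window_s` of the trace) and flags the cell when a run
#' of at least `min_spont_samples` supra-threshold samples falls entirely
#' outside every epoch's search window.
#'
#' @inheritParams epoch_threshold
#' @return `TRUE` if spontaneous activity is detected.
#' @export
detect_spontaneous <- function(dff, time, schedule, params = call_params()) {
  n <- length(time)
  w <- params$prestim_window_s
  x <- dff; x[is.na(x)] <- 0
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  lo <- findInterval(time - w, time) + 1  # first index with time >= t - w
  hi <- seq_len(n) - 1                    # window excludes the sample itself
  cnt <- hi - lo + 1
  valid <- cnt >= 5
  sum1 <- ifelse(hi >= 1, s1[pmax(hi, 1)], 0) -
    ifelse(lo >= 2, s1[pmax(lo - 1, 1)], 0)
  sum2 <- ifelse(hi >= 1, s2[pmax(hi, 1)], 0) -
    ifelse(lo >= 2, s2[pmax(lo - 1, 1)], 0)
  mu <- sum1 / cnt
  va <- pmax(0, (sum2 - cnt * mu^2) / (cnt - 1))
  thr <- mu + params$k_sd * sqrt(va)
  above <- valid & x > thr

  outside <- rep(TRUE, n)
  for (j in seq_len(nrow(schedule))) {
    v <- schedule$valve_open_s[j]
    outside <- outside & !(time >= v & time <= v + params$search_window_s)
  }
  r <- rle(above & outside)
  any(r$values & r$lengths >= params$min_spont_samples)
}

#' Apply vehicle-control and spontaneous-activity exclusions
#'
#' Cells whose Ringer (vehicle) call is responsive are flagged
#' `ringer_responsive` on every call; cells with detected spontaneous
#' activity are flagged `spontaneous_activity`. Excluded cells' calls are
#' set non-responsive, so exclusions only ever remove cells from analysis.
#'
#' @param calls Calls data frame (one row per cell x epoch).
#' @param normalized The `ca_normalized` the calls came from.
#' @param params [call_params()].
#' @return The calls with `exclusion_reason` set and `responsive` cleared
#'   for excluded cells.
#' @export
apply_exclusions <- function(calls, normalized, params = call_params()) {
  sched <- normalized$schedule
  excluded <- character(0)
  reason <- character(0)
  if (params$ringer_policy) {
    ringer_eps <- sched$epoch_id[sched$role == "vehicle_control"]
    if (!length(ringer_eps))
      stop("configuration error: ringer_policy is on but the schedule has ",
           "no vehicle_control epoch")
    bad <- unique(calls$cell_id[calls$epoch_id %in% ringer_eps &
                                  calls$responsive])
    excluded <- c(excluded, bad)
    reason <- c(reason, rep("ringer_responsive", length(bad)))
  }
  if (params$spontaneous_policy) {
    for (i in seq_along(normalized$cell_ids)) {
      id <- normalized$cell_ids[i]
      if (id %in% excluded) next
      if (detect_spontaneous(normalized$dff[i, ], normalized$time, sched,
                             params)) {
        excluded <- c(excluded, id)
        reason <- c(reason, "spontaneous_activity")
      }
    }
  }
  if (length(excluded)) {
    m <- match(calls$cell_id, excluded)
    hit <- !is.na(m)
    calls$exclusion_reason[hit] <- reason[m[hit]]
    calls$responsive[hit] <- FALSE
  }
  calls
}

#' Call every (cell, epoch) pair of a normalized recording
#'
#' Runs [call_epoch()] for every cell and schedule epoch, then (by default)
#' applies the exclusions of [apply_exclusions()].
#'
#' @param normalized A `ca_normalized` from [compute_dff()] or
#'   [normalize_recording()].
#' @param params [call_params()].
#' @param exclusions Apply vehicle/spontaneous exclusions (default `TRUE`).
#' @return Data frame of calls, one row per (cell, epoch).
#' @export
call_recording <- function(normalized, params = call_params(),
                           exclusions = TRUE) {
  stopifnot(inherits(normalized, "ca_normalized"))
  sched <- normalized$schedule
  if (is.null(sched)) stop("normalized recording has no schedule")
  rows <- vector("list", length(normalized$cell_ids) * nrow(sched))
  k <- 0
  for (i in seq_along(normalized$cell_ids)) {
    for (j in seq_len(nrow(sched))) {
      k <- k + 1
      row <- call_epoch(normalized$dff[i, ], normalized$time, sched,
                        sched$epoch_id[j], params)
      row$cell_id <- normalized$cell_ids[i]
      rows[[k]] <- row
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  if (exclusions) calls <- apply_exclusions(calls, normalized, params)
  calls
}

#' Summarize onset delays for a compound
#'
#' Mean, standard error and n of the valve-to-onset delay over responsive
#' calls for one compound.
#'
#' @param calls Calls data frame.
#' @param compound Compound name.
#' @return List `mean`, `sem` (`NA` for n = 1), `n`; all-`NA`/0 when there
#'   are no responsive calls.
#' @export
onset_delay_summary <- function(calls, compound) {
  d <- calls$onset_delay_s[calls$compound == compound & calls$responsive]
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0) return(list(mean = NA_real_, sem = NA_real_, n = 0L))
  list(mean = mean(d),
       sem = if (n > 1) stats::sd(d) / sqrt(n) else NA_real_,
       n = n)
}
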