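# Independent oracles and fixture builders shared across the test files.

# Brute-force response-call oracle: an explicit scan over every run of
# consecutive supra-threshold samples, written independently of call_epoch.
# Duration counts one sampling period per sample in the run.
oracle_call <- function(dff, time, valve, search_window, prestim_window,
                        k_sd, min_duration) {
  dt <- time[2] - time[1]
  base <- dff[time >= valve - prestim_window & time < valve]
  thr <- mean(base) + k_sd * sd(base)
  runs <- list()
  i <- 1
  n <- length(time)
  while (i <= n) {
    if (time[i] >= valve && !is.na(dff[i]) && dff[i] > thr) {
      j <- i
      while (j < n && !is.na(dff[j + 1]) && dff[j + 1] > thr) j <- j + 1
      runs[[length(runs) + 1]] <- c(start = i, len = j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  responsive <- FALSE; onset_idx <- NA_integer_; dur <- NA_real_
  for (r in runs) {
    if (time[r["start"]] > valve + search_window) next
    if (r["len"] * dt < min_duration - 1e-9) next
    if (!responsive) onset_idx <- unname(r["start"])
    responsive <- TRUE
    dur <- max(dur, r["len"] * dt, na.rm = TRUE)
  }
  search <- time >= valve & time <= valve + search_window
  list(responsive = responsive, threshold = thr, onset_idx = onset_idx,
       duration = dur, peak = max(dff[search], na.rm = TRUE))
}

# Single-epoch schedule for constructed-trace tests
one_epoch_schedule <- function(valve = 60, compound = "ATP",
                               role = "viability_control",
                               concentration = 0.03) {
  stim_schedule(compound = compound, concentration_mM = concentration,
                valve_open_s = valve, duration_s = 10, role = role)
}

# Profile table with given responder structure: `keys` are profile keys
# ("" for ATP-only), `counts` the matching cell counts; n_nonviable cells
# are appended as non-ATP-responsive.
make_profiles <- function(keys, counts, n_nonviable = 0) {
  keys <- rep(keys, counts)
  n <- length(keys) + n_nonviable
  data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    atp_responsive = c(rep(TRUE, length(keys)), rep(FALSE, n_nonviable)),
    responded_to = c(keys, rep("", n_nonviable)),
    profile_key = c(keys, rep("", n_nonviable)),
    stringsAsFactors = FALSE)
}

# Minimal calls table for population-analysis tests
make_calls <- function(cell_id, compound, responsive, epoch_id = NULL,
                       peak_dff = 0.5, exclusion = "none") {
  if (is.null(epoch_id)) epoch_id <- as.integer(factor(compound))
  n <- max(length(cell_id), length(compound), length(responsive))
  data.frame(cell_id = rep(cell_id, length.out = n),
             epoch_id = rep(epoch_id, length.out = n),
             compound = rep(compound, length.out = n),
             responsive = rep(responsive, length.out = n),
             peak_dff = rep(peak_dff, length.out = n),
             peak_time_s = rep(NA_real_, n), onset_time_s = rep(NA_real_, n),
             onset_delay_s = rep(NA_real_, n),
             suprathreshold_duration_s = rep(NA_real_, n),
             threshold = rep(0.05, n),
             exclusion_reason = rep(exclusion, length.out = n),
             stringsAsFactors = FALSE)
}

# All-non-responder generator config (bleach-fit studies)
nonresponder_config <- function(n_cells = 20, noise_sd = 0.02, ...) {
  synth_config(
    n_cells = n_cells, noise_sd = noise_sd,
    class_probabilities = c(non_responder = 1, atp_only = 0,
                            atp_denatonium = 0, atp_sweetener = 0,
                            atp_both = 0, ringer_artifact = 0,
                            spontaneous = 0), ...)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
enum_u_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
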