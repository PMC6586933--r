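#' Perfusion solution-exchange kernel
#'
#' Gravity-fed perfusion does not deliver a stimulus instantaneously: there is
#' a dead time between valve opening and stimulus arrival at the tissue, then
#' a gradual bath exchange. Calibration with fluorescein in these slice
#' chambers gives roughly a 4 s delay and a complete exchange in about 10 s;
#' the kernel is modelled as a piecewise-linear ramp between the two.
#'
#' @param t_since_valve Numeric vector, seconds since valve opening (negative
#'   values are valid pre-stimulus times and return 0).
#' @param delay_s Valve-to-tissue dead time in seconds (default 4).
#' @param full_exchange_s Time to complete solution exchange in seconds
#'   (default 10); must exceed `delay_s`.
#' @return Fraction of the final stimulus concentration at the tissue, in
#'   \[0, 1\], non-decreasing in `t_since_valve`.
#' @examples
#' perfusion_kernel(c(2, 7, 10), delay_s = 4, full_exchange_s = 10)
#' @export
perfusion_kernel <- function(t_since_valve, delay_s = 4, full_exchange_s = 10) {
  if (!(delay_s < full_exchange_s))
    stop("perfusion delay_s must be smaller than full_exchange_s")
  pmin(1, pmax(0, (t_since_valve - delay_s) / (full_exchange_s - delay_s)))
}

#' Canonical calcium transient shape
#'
#' A normalized difference of exponentials — the standard surrogate for a
#' calcium-indicator transient: zero before onset, a rise with time constant
#' `rise_tau`, a decay back to baseline with `decay_tau`. The shape is
#' rescaled so its analytic maximum equals `peak` exactly; the maximum occurs
#' at `onset + log(decay/rise) * rise * decay / (decay - rise)`.
#'
#' @param time Numeric vector, the recording time axis in seconds.
#' @param onset Transient onset time in seconds.
#' @param rise_tau,decay_tau Rise and decay time constants in seconds;
#'   `rise_tau < decay_tau` is required.
#' @param peak Peak amplitude in dF/F0 units (>= 0).
#' @return Numeric vector of dF/F0 values along `time`.
#' @export
make_transient <- function(time, onset, rise_tau, decay_tau, peak) {
  if (rise_tau >= decay_tau)
    stop("make_transient requires rise_tau < decay_tau")
  if (peak < 0) stop("make_transient requires peak >= 0")
  s <- numeric(length(time))
  if (peak == 0) return(s)
  u <- time - onset
  on <- u > 0
  if (!any(on)) return(s)
  t_star <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  m <- exp(-t_star / decay_tau) - exp(-t_star / rise_tau)
  s[on] <- peak * (exp(-u[on] / decay_tau) - exp(-u[on] / rise_tau)) / m
  s
}

#' Hill occupancy for concentration scaling
#'
#' `c^n / (c^n + ec50^n)`: the fraction of the saturating response evoked at
#' concentration `c`, used by the generator to scale transient peaks with
#' dose.
#'
#' @param concentration Concentration in mM (> 0).
#' @param ec50 Half-maximal concentration in mM (> 0).
#' @param n_hill Hill coefficient (> 0).
#' @return Fraction in (0, 1).
#' @examples
#' hill_scale(1, ec50 = 3, n_hill = 1)  # 0.25
#' @export
hill_scale <- function(concentration, ec50, n_hill) {
  if (any(concentration <= 0) || ec50 <= 0 || n_hill <= 0)
    stop("hill_scale requires positive concentration, ec50 and n_hill")
  cn <- concentration^n_hill
  cn / (cn + ec50^n_hill)
}

default_transient_params <- function() {
  # Onset delays are from valve opening: ~4 s perfusion dead time plus a
  # second-messenger (PLC/IP3) latency; means and spread follow the measured
  # 11.0 +/- 0.2 s (ATP) and 12.1 +/- 0.6 s (denatonium) sem values at n = 8.
  list(
    ATP        = list(onset_mean = 11.0, onset_sd = 1.7, rise_tau = 3,
                      decay_tau = 12, peak_mean = 0.8, peak_sd = 0.25),
    denatonium = list(onset_mean = 12.1, onset_sd = 1.7, rise_tau = 3,
                      decay_tau = 12, peak_mean = 0.8, peak_sd = 0.25),
    saccharin  = list(onset_mean = 12.0, onset_sd = 1.7, rise_tau = 3,
                      decay_tau = 12, peak_mean = 0.7, peak_sd = 0.25),
    sucralose  = list(onset_mean = 12.0, onset_sd = 1.7, rise_tau = 3,
                      decay_tau = 12, peak_mean = 0.7, peak_sd = 0.25),
    `acesulfame-K` = list(onset_mean = 12.0, onset_sd = 1.7, rise_tau = 3,
                      decay_tau = 12, peak_mean = 0.7, peak_sd = 0.25)
  )
}

default_hill_params <- function() {
  # EC50/n solved so 1 mM denatonium gives exactly 50% of the 10 mM peak and
  # 5 mM saccharin exactly 40% of the 10 mM peak.
  list(
    ATP        = list(ec50 = 0.01, n_hill = 1),
    denatonium = list(ec50 = 1.25, n_hill = 1),
    saccharin  = list(ec50 = 10,   n_hill = 2),
    sucralose  = list(ec50 = 10,   n_hill = 1),
    `acesulfame-K` = list(ec50 = 10, n_hill = 1)
  )
}

default_schedule <- function() {
  stim_schedule(
    compound = c("Ringer", "ATP", "denatonium", "saccharin"),
    concentration_mM = c(0, 0.03, 5, 10),
    valve_open_s = c(30, 120, 210, 300),
    duration_s = 10,
    role = c("vehicle_control", "viability_control", "test", "test")
  )
}

#' Configuration for the synthetic-recording generator
#'
#' Defines the study conditions a generated slice recording emulates: the
#' sampling rate and duration, the stimulus schedule, the mixture of cell
#' classes, per-compound transient kinetics and dose scaling, multiplicative
#' exponential photobleaching, additive Gaussian noise, and the perfusion
#' kernel. Defaults follow the slice-perfusion conditions the pipeline was
#' built for: 2 Hz sampling, ~70% of cells viable (ATP-responsive), of those
#' ~39% denatonium responders, ~28% sweetener (saccharin) responders with an
#' overlapping both-responsive subpopulation, plus small Ringer-artifact and
#' spontaneously active fractions.
#'
#' @param n_cells Number of cells.
#' @param sampling_rate_hz Acquisition rate in Hz (1-2 Hz typical; default 2).
#' @param duration_s Recording length in seconds; must cover every epoch's
#'   search window.
#' @param schedule A [stim_schedule()].
#' @param class_probabilities Named probabilities (summing to 1) over cell
#'   classes `non_responder`, `atp_only`, `atp_denatonium`, `atp_sweetener`,
#'   `atp_both`, `ringer_artifact`, `spontaneous`.
#' @param transient_params Per-compound list: `onset_mean`, `onset_sd`
#'   (seconds from valve opening), `rise_tau`, `decay_tau` (s), `peak_mean`,
#'   `peak_sd` (dF/F0).
#' @param hill_params Per-compound `ec50` (mM) and `n_hill`, used to scale
#'   peaks with concentration relative to the schedule's reference dose.
#' @param bleach_amplitude Bleached fraction A in \[0, 1); 0 disables.
#' @param bleach_tau_s Bleaching time constant in seconds (> 0).
#' @param noise_sd Additive Gaussian noise SD on the dF/F0 scale.
#' @param f0_mean,f0_sd Per-cell baseline fluorescence (arbitrary units).
#' @param perfusion_delay_s,full_exchange_s Perfusion kernel parameters, see
#'   [perfusion_kernel()].
#' @param spont_rate_range Integer range of transients emitted by a
#'   spontaneously active cell over the recording.
#' @param seed Integer seed; the same config and seed reproduce the recording
#'   bit for bit.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 400,
                         sampling_rate_hz = 2,
                         duration_s = 380,
                         schedule = default_schedule(),
                         class_probabilities = c(
                           non_responder = 0.24,
                           atp_only = 0.305,
                           atp_denatonium = 0.20,
                           atp_sweetener = 0.125,
                           atp_both = 0.07,
                           ringer_artifact = 0.02,
                           spontaneous = 0.04),
                         transient_params = default_transient_params(),
                         hill_params = default_hill_params(),
                         bleach_amplitude = 0.2,
                         bleach_tau_s = 300,
                         noise_sd = 0.02,
                         f0_mean = 100, f0_sd = 20,
                         perfusion_delay_s = 4,
                         full_exchange_s = 10,
                         spont_rate_range = c(1L, 3L),
                         seed = 1L,
                         search_window_s = 60) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  classes <- c("non_responder", "atp_only", "atp_denatonium", "atp_sweetener",
               "atp_both", "ringer_artifact", "spontaneous")
  p <- cfg$class_probabilities
  if (!setequal(names(p), classes))
    stop("class_probabilities must be named exactly: ",
         paste(classes, collapse = ", "))
  if (abs(sum(p) - 1) > 1e-9)
    stop("class_probabilities must sum to 1 (got ", sum(p), ")")
  if (any(p < 0)) stop("class_probabilities must be non-negative")
  if (cfg$sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$bleach_tau_s <= 0) stop("bleach_tau_s must be > 0")
  if (cfg$bleach_amplitude < 0 || cfg$bleach_amplitude >= 1)
    stop("bleach_amplitude must be in [0, 1)")
  for (nm in names(cfg$transient_params)) {
    tp <- cfg$transient_params[[nm]]
    if (tp$rise_tau <= 0 || tp$decay_tau <= 0 || tp$rise_tau >= tp$decay_tau)
      stop("transient_params for ", nm, ": need 0 < rise_tau < decay_tau")
  }
  validate_schedule(cfg$schedule)
  need <- max(cfg$schedule$valve_open_s) + cfg$search_window_s
  if (cfg$duration_s < need)
    stop("duration_s (", cfg$duration_s, ") too short for the schedule; ",
         "need >= ", need, " s to cover every epoch search window")
  invisible(cfg)
}

# compounds a given class responds to (sweetener = any non-ATP, non-denatonium
# test tastant in the schedule)
class_compounds <- function(class, schedule) {
  tastants <- unique(schedule$compound[schedule$role == "test"])
  sweeteners <- setdiff(tastants, "denatonium")
  switch(class,
    non_responder = character(0),
    atp_only = "ATP",
    atp_denatonium = c("ATP", intersect("denatonium", tastants)),
    atp_sweetener = c("ATP", sweeteners),
    atp_both = c("ATP", tastants),
    ringer_artifact = c("ATP", "Ringer"),
    spontaneous = "ATP",
    stop("unknown cell class: ", class))
}

# reference (top) concentration per compound in a schedule, for Hill scaling
reference_concentration <- function(schedule) {
  ref <- tapply(schedule$concentration_mM, schedule$compound, max)
  as.list(ref)
}

#' Generate a ground-truth-labelled synthetic recording
#'
#' Simulates raw fluorescence for a population of cells under the stimulus
#' schedule in `config`. Each cell draws a class from
#' `class_probabilities`; responsive (cell, epoch) pairs receive one calcium
#' transient with onset sampled around valve opening plus the compound's
#' configured delay (truncated at the perfusion dead time) and peak scaled by
#' Hill occupancy at the epoch's concentration. Ringer-artifact cells also
#' respond during vehicle epochs (emulating movement artifacts);
#' spontaneously active cells emit 1-3 transients at random times outside all
#' epoch search windows. Raw fluorescence is
#' `F0 * (1 - A + A * exp(-t / tau_b)) * (1 + dff(t)) + F0 * noise`,
#' i.e. signal and baseline bleach together and noise is additive Gaussian,
#' i.i.d. per sample.
#'
#' @param config A [synth_config()].
#' @return A list with elements `recording` (a [ca_recording()]) and `truth`
#'   (class `ca_truth`): `truth$cells` has one row per cell (`cell_id`,
#'   `class`, `f0`, `bleach_amplitude`, `bleach_tau_s`), `truth$events` one
#'   row per generated transient (`cell_id`, `epoch_id` — `NA` for
#'   spontaneous events, `compound`, `true_onset_s`, `true_peak_dff`).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  with_seed(config$seed, generate_recording_impl(config))
}

generate_recording_impl <- function(cfg) {
  dt <- 1 / cfg$sampling_rate_hz
  time <- seq(0, cfg$duration_s, by = dt)
  sched <- cfg$schedule
  n <- cfg$n_cells
  classes <- sample(names(cfg$class_probabilities), n, replace = TRUE,
                    prob = cfg$class_probabilities)
  cell_ids <- sprintf("cell_%03d", seq_len(n))
  f0 <- pmax(1, rnorm(n, cfg$f0_mean, cfg$f0_sd))
  ref <- reference_concentration(sched)

  events <- vector("list", n)
  dff <- matrix(0, n, length(time))
  for (i in seq_len(n)) {
    resp <- class_compounds(classes[i], sched)
    ev <- list()
    for (j in seq_len(nrow(sched))) {
      comp <- sched$compound[j]
      if (!comp %in% resp) next
      if (comp == "Ringer") {
        # movement artifact: modest transient locked to solution switching
        tp <- list(onset_mean = cfg$perfusion_delay_s + 2, onset_sd = 1,
                   rise_tau = 2, decay_tau = 8, peak_mean = 0.4, peak_sd = 0.1)
        scale <- 1
      } else {
        tp <- cfg$transient_params[[comp]]
        if (is.null(tp)) next
        hp <- cfg$hill_params[[comp]]
        scale <- if (is.null(hp)) 1 else
          hill_scale(sched$concentration_mM[j], hp$ec50, hp$n_hill) /
          hill_scale(ref[[comp]], hp$ec50, hp$n_hill)
      }
      onset_delay <- rnorm_trunc(1, tp$onset_mean, tp$onset_sd,
                                 lower = cfg$perfusion_delay_s,
                                 upper = cfg$search_window_s - 1)
      onset <- sched$valve_open_s[j] + onset_delay
      peak <- max(0.2, rnorm(1, tp$peak_mean, tp$peak_sd)) * scale
      dff[i, ] <- dff[i, ] + make_transient(time, onset, tp$rise_tau,
                                            tp$decay_tau, peak)
      ev[[length(ev) + 1]] <- data.frame(
        cell_id = cell_ids[i], epoch_id = sched$epoch_id[j], compound = comp,
        true_onset_s = onset, true_peak_dff = peak, stringsAsFactors = FALSE)
    }
    if (classes[i] == "spontaneous") {
      k <- sample(seq(cfg$spont_rate_range[1], cfg$spont_rate_range[2]), 1)
      gaps <- inter_epoch_gaps(sched, time, cfg$search_window_s)
      for (g in seq_len(k)) {
        onset <- runif_in_intervals(1, gaps)
        if (is.na(onset)) next
        peak <- max(0.2, rnorm(1, 0.6, 0.2))
        dff[i, ] <- dff[i, ] + make_transient(time, onset, 3, 10, peak)
        ev[[length(ev) + 1]] <- data.frame(
          cell_id = cell_ids[i], epoch_id = NA_integer_,
          compound = "spontaneous", true_onset_s = onset,
          true_peak_dff = peak, stringsAsFactors = FALSE)
      }
    }
    events[[i]] <- if (length(ev)) do.call(rbind, ev) else NULL
  }

  bleach <- 1 - cfg$bleach_amplitude +
    cfg$bleach_amplitude * exp(-time / cfg$bleach_tau_s)
  raw <- f0 * t(apply(1 + dff, 1, function(s) s * bleach))
  if (cfg$noise_sd > 0)
    raw <- raw + f0 * matrix(rnorm(length(raw), 0, cfg$noise_sd),
                             nrow = n)

  rec <- ca_recording(time, raw, cell_ids, sched,
                      metadata = list(sampling_rate_hz = cfg$sampling_rate_hz,
                                      synthetic = TRUE, seed = cfg$seed))
  ev_all <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(ev_all))
    ev_all <- data.frame(cell_id = character(0), epoch_id = integer(0),
                         compound = character(0), true_onset_s = numeric(0),
                         true_peak_dff = numeric(0))
  rownames(ev_all) <- NULL
  truth <- structure(list(
    cells = data.frame(cell_id = cell_ids, class = classes, f0 = f0,
                       bleach_amplitude = cfg$bleach_amplitude,
                       bleach_tau_s = cfg$bleach_tau_s,
                       stringsAsFactors = FALSE),
    events = ev_all), class = "ca_truth")
  list(recording = rec, truth = truth)
}

# gaps between [valve, valve + search] windows, clipped to the time range.
# Placement keeps events identifiable: a 15 s baseline must precede the
# onset (so the first gap starts no earlier than 15 s into the recording)
# and the onset stays >= 5 s clear of the next stimulus window.
inter_epoch_gaps <- function(sched, time, search_window_s) {
  win <- cbind(sched$valve_open_s, sched$valve_open_s + search_window_s)
  bounds <- sort(c(time[1], t(win), time[length(time)]))
  gaps <- matrix(bounds, ncol = 2, byrow = TRUE)
  gaps[, 1] <- pmax(gaps[, 1], time[1] + 15)
  gaps[, 2] <- gaps[, 2] - 5
  gaps[gaps[, 2] - gaps[, 1] > 0, , drop = FALSE]
}

runif_in_intervals <- function(n, intervals) {
  if (nrow(intervals) == 0) return(NA_real_)
  len <- intervals[, 2] - intervals[, 1]
  i <- sample.int(nrow(intervals), n, replace = TRUE, prob = len)
  runif(n, intervals[i, 1], intervals[i, 2])
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# evaluate thunk under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Render a recording as a synthetic image stack plus ROI label mask
#'
#' Places one square ROI per cell on a grid inside the frame and fills its
#' pixels, frame by frame, with the cell's raw fluorescence plus independent
#' per-pixel Gaussian noise; background pixels hold a constant offset. The
#' pixel mean over an ROI therefore equals the cell's trace up to a standard
#' error of `pixel_noise_sd * F0 / sqrt(pixels per ROI)`.
#'
#' @param recording A [ca_recording()].
#' @param frame_dim Frame height/width in pixels, `c(h, w)`.
#' @param roi_size Side length of each square ROI in pixels.
#' @param pixel_noise_sd Per-pixel Gaussian noise SD as a fraction of the
#'   trace value's scale (applied as `pixel_noise_sd * mean(trace)`); 0 for
#'   noiseless pixels.
#' @param background Background pixel value (arbitrary units).
#' @param seed Integer seed for the per-pixel noise.
#' @return List with `stack` (array `h x w x frames`) and `mask` (integer
#'   matrix `h x w`; 0 = background, ROI ids 1..n matching cell order).
#' @export
generate_stack <- function(recording, frame_dim = c(64, 64), roi_size = 8,
                           pixel_noise_sd = 0, background = 10, seed = 1L) {
  n <- nrow(recording$traces)
  h <- frame_dim[1]; w <- frame_dim[2]
  gap <- 2
  per_row <- (w - gap) %/% (roi_size + gap)
  n_rows <- (h - gap) %/% (roi_size + gap)
  if (per_row < 1 || n > per_row * n_rows)
    stop("geometry error: frame too small to place ", n,
         " non-overlapping ROIs of size ", roi_size)
  mask <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% per_row
    c0 <- (i - 1) %% per_row
    rows <- gap + r * (roi_size + gap) + seq_len(roi_size)
    cols <- gap + c0 * (roi_size + gap) + seq_len(roi_size)
    mask[rows, cols] <- i
  }
  nt <- ncol(recording$traces)
  with_seed(seed, {
    stack <- array(background, dim = c(h, w, nt))
    idx <- which(mask > 0)
    lab <- mask[idx]
    for (f in seq_len(nt)) {
      frame <- matrix(background, h, w)
      vals <- recording$traces[lab, f]
      if (pixel_noise_sd > 0)
        vals <- vals + rnorm(length(vals),
                             0, pixel_noise_sd * mean(recording$traces[, f]))
      frame[idx] <- vals
      stack[, , f] <- frame
    }
    list(stack = stack, mask = mask)
  })
}
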