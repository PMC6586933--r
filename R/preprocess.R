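#' Baseline fluorescence before the first stimulus
#'
#' F0 is the arithmetic mean of each cell's raw fluorescence over the window
#' from the start of the recording to the first valve opening. Cells with a
#' non-positive baseline cannot be normalized and are rejected.
#'
#' @param recording A [ca_recording()] with a schedule.
#' @return Named numeric vector of per-cell F0 (arbitrary units). Rejected
#'   cells carry `NA` and are listed in `attr(, "rejected")`.
#' @export
compute_f0 <- function(recording) {
  if (is.null(recording$schedule))
    stop("compute_f0 needs a schedule to locate the first stimulus")
  first <- min(recording$schedule$valve_open_s)
  pre <- recording$time < first
  if (sum(pre) < 5)
    stop("insufficient baseline: only ", sum(pre),
         " samples before the first valve opening (need >= 5)")
  f0 <- rowMeans(recording$traces[, pre, drop = FALSE], na.rm = TRUE)
  bad <- f0 <= 0
  if (any(bad)) {
    warning("rejected ", sum(bad), " cell(s) with F0 <= 0: ",
            paste(recording$cell_ids[bad], collapse = ", "))
    f0[bad] <- NA_real_
  }
  names(f0) <- recording$cell_ids
  attr(f0, "rejected") <- recording$cell_ids[bad]
  f0
}

#' Normalize raw fluorescence to dF/F0
#'
#' Elementwise `(F(t) - F0) / F0` per cell. Cells with missing (rejected) F0
#' are dropped.
#'
#' @param recording A [ca_recording()].
#' @param f0 Per-cell baseline from [compute_f0()]; computed if missing.
#' @return A `ca_normalized` object: `time`, `dff` (cells x time), `f0`,
#'   `schedule`, `cell_ids`, `bleach_fit` (NULL until fitted), `corrected`.
#' @export
compute_dff <- function(recording, f0 = compute_f0(recording)) {
  if (length(f0) != nrow(recording$traces))
    stop("dimension error: f0 length != number of traces")
  keep <- !is.na(f0)
  dff <- (recording$traces[keep, , drop = FALSE] / f0[keep]) - 1
  structure(list(time = recording$time, dff = dff,
                 f0 = f0[keep], cell_ids = recording$cell_ids[keep],
                 schedule = recording$schedule,
                 recording = recording,
                 bleach_fit = NULL, corrected = FALSE),
            class = "ca_normalized")
}

#' Fit the photobleaching decay on non-responding cells
#'
#' Progressive indicator bleaching under illumination shows up as a slow
#' exponential sag common to all cells; cells with no stimulus response and
#' no spontaneous activity expose it uncontaminated. Each given
#' non-responder's raw trace is divided by its own F0, the traces are
#' averaged, samples inside any epoch search window are excluded (guarding
#' against sub-threshold stimulus contamination), and
#' `Fbar(t) = C + B * exp(-t / tau_b)` is fit by Levenberg-Marquardt least
#' squares.
#'
#' @param recording A [ca_recording()].
#' @param non_responder_ids Cell ids to pool (>= 3 required).
#' @param search_window_s Seconds after each valve opening to exclude from
#'   the fit (default 60).
#' @param tau_bounds Plausible range for `tau_b` in seconds; a fit outside it
#'   is flagged implausible and correction is disabled.
#' @return A `bleach_fit` list: `A` (bleached fraction `B / (B + C)`),
#'   `tau_b_s`, `C`, `B`, `rms_residual`, `cells_used`, `plausible`.
#' @export
fit_bleach <- function(recording, non_responder_ids,
                       search_window_s = 60, tau_bounds = c(1, 1e5)) {
  idx <- match(non_responder_ids, recording$cell_ids)
  if (anyNA(idx)) stop("unknown cell id(s): ",
                       paste(non_responder_ids[is.na(idx)], collapse = ", "))
  if (length(idx) < 3)
    stop("fit_bleach needs >= 3 non-responding cells, got ", length(idx))
  time <- recording$time
  if (length(time) < 20) stop("fit_bleach needs >= 20 samples")
  f0 <- compute_f0(recording)[idx]
  norm <- recording$traces[idx, , drop = FALSE] / f0
  ybar <- colMeans(norm, na.rm = TRUE)

  keep <- rep(TRUE, length(time))
  if (!is.null(recording$schedule))
    for (j in seq_len(nrow(recording$schedule))) {
      v <- recording$schedule$valve_open_s[j]
      keep <- keep & !(time >= v & time < v + search_window_s)
    }
  tt <- time[keep]; yy <- ybar[keep]

  c0 <- mean(yy[tt >= stats::quantile(tt, 0.9)])
  b0 <- mean(yy[tt <= stats::quantile(tt, 0.1)]) - c0
  tau0 <- (max(tt) - min(tt)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ C + B * exp(-tt / tau),
                      start = list(C = c0, B = b0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # flat pool: exponential amplitude is unidentifiable, report a no-op fit
    if (stats::sd(yy) < 1e-8) {
      co <- c(C = mean(yy), B = 0, tau = tau0)
      res <- yy - mean(yy)
    } else {
      stop("bleach fit did not converge: ", conditionMessage(fit),
           " (pooled-trace sd = ", signif(stats::sd(yy), 3), ")")
    }
  } else {
    co <- stats::coef(fit)
    res <- stats::residuals(fit)
  }
  total0 <- co[["C"]] + co[["B"]]          # fitted value at t = 0
  A <- if (total0 > 0) co[["B"]] / total0 else NA_real_
  plausible <- is.finite(co[["tau"]]) && co[["tau"]] > tau_bounds[1] &&
    co[["tau"]] < tau_bounds[2] && is.finite(A)
  structure(list(A = A, tau_b_s = co[["tau"]], C = co[["C"]], B = co[["B"]],
                 rms_residual = sqrt(mean(res^2)),
                 cells_used = recording$cell_ids[idx],
                 plausible = plausible),
            class = "bleach_fit")
}

# fitted decay normalized to 1 at t0
bleach_curve <- function(fit, time) {
  y <- fit$C + fit$B * exp(-time / fit$tau_b_s)
  y / (fit$C + fit$B * exp(-time[1] / fit$tau_b_s))
}

#' Correct a recording for photobleaching
#'
#' Divides each raw trace by the fitted decay curve (normalized to 1 at the
#' first sample), then recomputes F0 and dF/F0. On bleach-free data
#' (`B = 0`) this is the identity.
#'
#' @param normalized A `ca_normalized` from [compute_dff()].
#' @param bleach_fit A fit from [fit_bleach()].
#' @return A new `ca_normalized` with `corrected = TRUE` and the fit
#'   attached.
#' @export
correct_bleach <- function(normalized, bleach_fit) {
  stopifnot(inherits(bleach_fit, "bleach_fit"))
  if (!bleach_fit$plausible)
    stop("bleach fit flagged implausible (tau_b = ",
         signif(bleach_fit$tau_b_s, 3), " s); correction disabled")
  rec <- normalized$recording
  curve <- bleach_curve(bleach_fit, rec$time)
  if (any(curve <= 0))
    stop("correction error: fitted decay reaches <= 0 within the recording")
  corrected <- rec
  corrected$traces <- sweep(rec$traces, 2, curve, "/")
  out <- compute_dff(corrected)
  out$bleach_fit <- bleach_fit
  out$corrected <- TRUE
  out
}

#' One-shot normalization with automatic bleach handling
#'
#' The production entry point from raw recording to analysis-ready dF/F0.
#' `bleach = "auto"` runs a two-pass scheme: pass 1 normalizes and calls
#' responses without correction; cells with no responsive call, no Ringer
#' response and no spontaneous activity form the non-responder pool; the
#' decay is fitted on that pool and, if the bleached fraction `A` exceeds
#' `auto_threshold`, the recording is corrected and renormalized.
#'
#' @param recording A [ca_recording()].
#' @param params [call_params()] used for the pass-1 calls.
#' @param bleach `"auto"`, `"off"`, or a ready-made [fit_bleach()] result.
#' @param auto_threshold Minimum fitted bleached fraction A that triggers
#'   correction in auto mode (default 0.05).
#' @param min_pool Minimum number of non-responders required to attempt the
#'   fit in auto mode (default 3).
#' @return A `ca_normalized`, bleach-corrected when warranted.
#' @export
normalize_recording <- function(recording, params = call_params(),
                                bleach = "auto", auto_threshold = 0.05,
                                min_pool = 3) {
  norm <- compute_dff(recording)
  if (identical(bleach, "off")) return(norm)
  if (inherits(bleach, "bleach_fit")) return(correct_bleach(norm, bleach))
  if (!identical(bleach, "auto"))
    stop("bleach must be 'auto', 'off', or a bleach_fit object")
  calls <- call_recording(norm, params)
  resp_any <- tapply(calls$responsive | calls$exclusion_reason != "none",
                     calls$cell_id, any)
  pool <- names(resp_any)[!resp_any]
  if (length(pool) < min_pool) {
    warning("auto bleach correction skipped: only ", length(pool),
            " clean non-responders (need >= ", min_pool, ")")
    return(norm)
  }
  fit <- fit_bleach(recording, pool, search_window_s = params$search_window_s)
  if (!fit$plausible || !is.finite(fit$A) || fit$A < auto_threshold) {
    norm$bleach_fit <- fit
    return(norm)
  }
  correct_bleach(norm, fit)
}
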