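#' Build per-cell response profiles conditioned on viability
#'
#' Tastant analysis is conditioned on viability: only cells with a call for
#' the viability compound (ATP) are profiled, excluded cells are dropped, and
#' each remaining cell carries the set of test compounds it responded to.
#'
#' @param calls Calls data frame from [call_recording()].
#' @param viability_compound Compound of the viability control (default
#'   `"ATP"`).
#' @return Data frame with `cell_id`, `atp_responsive`, `responded_to`
#'   (comma-free `+`-joined canonical string, `""` for none), `profile_key`
#'   (same; kept separate for clarity), one row per analyzable cell.
#' @export
build_profiles <- function(calls, viability_compound = "ATP") {
  keep <- tapply(calls$exclusion_reason == "none", calls$cell_id, all)
  cells <- names(keep)[keep]
  dropped <- setdiff(unique(calls$cell_id), cells)
  calls <- calls[calls$cell_id %in% cells, , drop = FALSE]
  via <- calls[calls$compound == viability_compound, , drop = FALSE]
  no_via <- setdiff(cells, via$cell_id)
  if (length(no_via)) {
    warning("dropped ", length(no_via),
            " cell(s) without a viability (", viability_compound,
            ") call: ", paste(utils::head(no_via, 5), collapse = ", "))
    cells <- setdiff(cells, no_via)
  }
  atp <- stats::setNames(
    vapply(split(via$responsive, via$cell_id), any, logical(1))[cells], cells)
  test <- calls[calls$responsive &
                  !calls$compound %in% c(viability_compound, "Ringer"), ,
                drop = FALSE]
  resp_sets <- split(test$compound, test$cell_id)
  key <- vapply(cells, function(id) {
    s <- sort(unique(resp_sets[[id]]))
    paste(s, collapse = "+")
  }, character(1))
  # conditioning: a cell not viable contributes no tastant profile
  key[!atp] <- ""
  out <- data.frame(cell_id = cells, atp_responsive = unname(atp),
                    responded_to = unname(key), profile_key = unname(key),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

# half-up rounding to integer percent (report-table convention)
percent_display <- function(x) floor(x + 0.5)

#' Responder-frequency table over ATP-responsive cells
#'
#' One row per listed compound: the count of ATP-responsive cells responding
#' to it, the ATP-responsive denominator and the percentage; preceded by a
#' viability row (ATP-responsive cells over all analyzable cells) and
#' followed by profile-partition rows restricted to cells responding to at
#' least one listed compound.
#'
#' @param profiles From [build_profiles()].
#' @param compounds Test compounds to tabulate.
#' @param viability_compound Label used for the viability row.
#' @return Data frame `label, kind, count, denominator, percent,
#'   percent_display`.
#' @export
frequency_table <- function(profiles, compounds,
                            viability_compound = "ATP") {
  if (!nrow(profiles)) stop("frequency_table: empty profile list")
  n_all <- nrow(profiles)
  atp <- profiles[profiles$atp_responsive, , drop = FALSE]
  n_atp <- nrow(atp)
  if (n_atp == 0) stop("undefined percent: no viable (ATP-responsive) cells")
  rows <- list(data.frame(
    label = viability_compound, kind = "viability", count = n_atp,
    denominator = n_all, stringsAsFactors = FALSE))
  sets <- strsplit(atp$responded_to, "+", fixed = TRUE)
  for (cmp in compounds) {
    cnt <- sum(vapply(sets, function(s) cmp %in% s, logical(1)))
    rows[[length(rows) + 1]] <- data.frame(
      label = cmp, kind = "compound", count = cnt, denominator = n_atp,
      stringsAsFactors = FALSE)
  }
  # profile partition over cells responding to >= 1 listed compound
  inpanel <- vapply(sets, function(s) length(intersect(s, compounds)) > 0,
                    logical(1))
  panel_keys <- vapply(sets[inpanel], function(s)
    paste(sort(intersect(s, compounds)), collapse = "+"), character(1))
  n_panel <- sum(inpanel)
  if (n_panel > 0)
    for (k in sort(unique(panel_keys)))
      rows[[length(rows) + 1]] <- data.frame(
        label = k, kind = "profile", count = sum(panel_keys == k),
        denominator = n_panel, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$percent <- 100 * out$count / out$denominator
  out$percent_display <- percent_display(out$percent)
  out
}

#' Two-compound response-overlap (Venn) counts
#'
#' Over cells responding to at least one of the two compounds: the counts
#' responding only to the first, only to the second, and to both.
#'
#' @param profiles From [build_profiles()].
#' @param compound_a,compound_b Compound names.
#' @return List `only_a`, `only_b`, `both`, `total`.
#' @export
venn_counts <- function(profiles, compound_a, compound_b) {
  sets <- strsplit(profiles$responded_to[profiles$atp_responsive],
                   "+", fixed = TRUE)
  a <- vapply(sets, function(s) compound_a %in% s, logical(1))
  b <- vapply(sets, function(s) compound_b %in% s, logical(1))
  list(only_a = sum(a & !b), only_b = sum(!a & b), both = sum(a & b),
       total = sum(a | b))
}

#' Responsiveness retention across a treatment
#'
#' Among cells responsive to a compound before a treatment (e.g. the gap
#' junction blocker carbenoxolone), the number still responsive after it.
#'
#' @param calls_before,calls_after Calls data frames for the two phases,
#'   matched by `cell_id`.
#' @param compound Compound to assess.
#' @return List `n_retained`, `n_total`, `fraction`.
#' @export
retention_counts <- function(calls_before, calls_after, compound) {
  cb <- calls_before[calls_before$compound == compound, , drop = FALSE]
  ca <- calls_after[calls_after$compound == compound, , drop = FALSE]
  if (!setequal(cb$cell_id, ca$cell_id))
    stop("matching error: cell ids differ between before and after phases")
  before_resp <- cb$cell_id[cb$responsive]
  after_resp <- ca$cell_id[ca$responsive]
  n_total <- length(before_resp)
  n_ret <- length(intersect(before_resp, after_resp))
  list(n_retained = n_ret, n_total = n_total,
       fraction = if (n_total > 0) n_ret / n_total else NA_real_)
}

#' Within-cell dose-response normalization
#'
#' Each cell's peak dF/F0 at every tested concentration of a compound is
#' divided by its own peak at the reference (largest tested) concentration;
#' normalized peaks are then averaged across cells per concentration
#' (mean +/- sem). Cells lacking a responsive call at the reference
#' concentration are dropped.
#'
#' @param calls Calls data frame holding one call per (cell, concentration),
#'   with a `concentration_mM` column (joined from the schedule by
#'   [call_recording()] users via `merge`, or already present).
#' @param compound Compound name.
#' @param reference_concentration Reference dose in mM; defaults to the
#'   largest tested.
#' @return List with `per_cell` (long data frame `cell_id,
#'   concentration_mM, normalized_peak`) and `summary` (per concentration:
#'   `mean`, `sem`, `n`); `reference_concentration`.
#' @export
dose_response <- function(calls, compound, reference_concentration = NULL) {
  d <- calls[calls$compound == compound, , drop = FALSE]
  if (!"concentration_mM" %in% names(d))
    stop("dose_response needs a 'concentration_mM' column on the calls")
  if (is.null(reference_concentration))
    reference_concentration <- max(d$concentration_mM)
  per <- list()
  for (id in unique(d$cell_id)) {
    di <- d[d$cell_id == id, , drop = FALSE]
    ref <- di[di$concentration_mM == reference_concentration, , drop = FALSE]
    if (!nrow(ref) || !any(ref$responsive)) {
      warning("cell ", id, " lacks a responsive reference-dose call; dropped")
      next
    }
    per[[id]] <- data.frame(
      cell_id = id, concentration_mM = di$concentration_mM,
      normalized_peak = di$peak_dff / ref$peak_dff[1],
      stringsAsFactors = FALSE)
  }
  per_cell <- if (length(per)) do.call(rbind, per) else
    data.frame(cell_id = character(0), concentration_mM = numeric(0),
               normalized_peak = numeric(0))
  rownames(per_cell) <- NULL
  sm <- NULL
  if (nrow(per_cell)) {
    sp <- split(per_cell$normalized_peak, per_cell$concentration_mM)
    sm <- data.frame(
      concentration_mM = as.numeric(names(sp)),
      mean = vapply(sp, mean, numeric(1)),
      sem = vapply(sp, function(x)
        if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
        numeric(1)),
      n = vapply(sp, length, integer(1)))
    rownames(sm) <- NULL
  }
  list(per_cell = per_cell, summary = sm,
       reference_concentration = reference_concentration)
}

#' Normalize repeated-stimulation peaks to the first stimulation
#'
#' For pharmacology comparisons where the same cell is stimulated repeatedly
#' (control vs Ca2+-free, PLC inhibitor, ...): every stimulation's peak is
#' divided by that cell's first-stimulation peak, so the first value is
#' exactly 1. Cells whose first stimulation is non-responsive are dropped.
#'
#' @param calls Calls for one compound, >= 2 stimulations per cell, ordered
#'   by epoch (`epoch_id` ascending = stimulation order).
#' @param compound Compound name.
#' @return Long data frame `cell_id, stimulation, peak_dff,
#'   normalized_peak`.
#' @export
normalize_to_first <- function(calls, compound) {
  d <- calls[calls$compound == compound, , drop = FALSE]
  d <- d[order(d$cell_id, d$epoch_id), ]
  out <- list()
  for (id in unique(d$cell_id)) {
    di <- d[d$cell_id == id, , drop = FALSE]
    if (nrow(di) < 2) {
      warning("cell ", id, " has < 2 stimulations of ", compound, "; dropped")
      next
    }
    if (!di$responsive[1]) {
      warning("cell ", id, " first stimulation non-responsive; dropped")
      next
    }
    out[[id]] <- data.frame(
      cell_id = id, stimulation = seq_len(nrow(di)), peak_dff = di$peak_dff,
      normalized_peak = di$peak_dff / di$peak_dff[1],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = character(0), stimulation = integer(0),
               peak_dff = numeric(0), normalized_peak = numeric(0))
  rownames(res) <- NULL
  res
}

#' Heat-map matrix ordered by response profile
#'
#' Rows are cells sorted by profile key, then by their maximum dF/F0
#' descending within a profile group; the returned boundary indices mark the
#' divisions between profile groups (the thin black lines of a profile heat
#' map).
#'
#' @param normalized A `ca_normalized`.
#' @param profiles From [build_profiles()].
#' @return List `matrix` (cells x time dF/F0, rownames = cell ids),
#'   `groups` (profile key per row), `boundaries` (row indices after which
#'   a new profile group starts).
#' @export
heatmap_matrix <- function(normalized, profiles) {
  ids <- intersect(normalized$cell_ids, profiles$cell_id)
  if (!length(ids))
    return(list(matrix = normalized$dff[0, , drop = FALSE],
                groups = character(0), boundaries = integer(0)))
  pk <- profiles$profile_key[match(ids, profiles$cell_id)]
  amp <- apply(normalized$dff[match(ids, normalized$cell_ids), ,
                              drop = FALSE], 1, max, na.rm = TRUE)
  o <- order(pk, -amp, ids)
  ids <- ids[o]; pk <- pk[o]
  m <- normalized$dff[match(ids, normalized$cell_ids), , drop = FALSE]
  rownames(m) <- ids
  boundaries <- which(diff(as.integer(factor(pk, levels = unique(pk)))) != 0)
  list(matrix = m, groups = pk, boundaries = boundaries)
}
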