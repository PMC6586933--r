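#' Read an analysis configuration file
#'
#' YAML or JSON (by extension). Recognized top-level blocks: `synth`
#' (arguments of [synth_config()], with `schedule` as a list of epoch
#' records), `call` (arguments of [call_params()]), `bleach_correction`
#' (`"auto"` / `"off"`), `viability_compound`.
#'
#' @param path Config file path.
#' @return Named list with defaults filled in.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  raw
}

config_synth <- function(cfg, seed = NULL) {
  args <- cfg$synth
  if (is.null(args)) args <- list()
  if (!is.null(args$schedule) && !inherits(args$schedule, "ca_schedule"))
    args$schedule <- do.call(stim_schedule, as.list(args$schedule))
  if (!is.null(args$class_probabilities))
    args$class_probabilities <- unlist(args$class_probabilities)
  if (!is.null(seed)) args$seed <- seed
  do.call(synth_config, args)
}

config_call_params <- function(cfg) {
  args <- cfg$call
  if (is.null(args)) args <- list()
  do.call(call_params, args)
}

#' Pipeline steps: simulate, extract, call, analyze
#'
#' Thin, file-oriented wrappers around the package's functions so a whole
#' run is reproducible from a config file and a seed. `run_simulate` writes
#' `traces.csv`, `traces_schedule.csv` and `truth.csv`; `run_extract` reads
#' a TIFF stack + mask and writes `traces.csv`; `run_call` writes
#' `calls.csv`; `run_analyze` writes `frequencies.csv`, `venn.csv` and
#' `summary.json`. Identical config and seed give byte-identical outputs.
#'
#' @param config Config list from [read_config()] (or an empty list for
#'   defaults).
#' @param out_dir Output directory, created if missing.
#' @param seed Integer seed overriding the config's.
#' @return Invisibly, the paths written (or for `run_call`/`run_analyze`
#'   the main result object).
#' @export
run_simulate <- function(config = list(), out_dir = ".", seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config_synth(config, seed)
  gen <- generate_recording(scfg)
  tp <- file.path(out_dir, "traces.csv")
  write_traces(gen$recording, tp)
  write_truth(gen$truth, file.path(out_dir, "truth.csv"))
  invisible(c(traces = tp,
              schedule = file.path(out_dir, "traces_schedule.csv"),
              truth = file.path(out_dir, "truth.csv")))
}

#' @rdname run_simulate
#' @param stack_path,mask_path TIFF stack and label-mask paths.
#' @param sampling_rate_hz Sampling rate of the stack (frames per second).
#' @export
run_extract <- function(stack_path, mask_path, config = list(),
                        out_dir = ".", sampling_rate_hz = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- read_stack(stack_path)
  mask <- read_mask(mask_path)
  sched <- NULL
  sc <- paste0(sub("\\.[^.]*$", "", stack_path), "_schedule.csv")
  if (file.exists(sc)) sched <- read_schedule(sc)
  rec <- extract_rois(stack, mask, schedule = sched,
                      sampling_rate_hz = sampling_rate_hz)
  tp <- file.path(out_dir, "traces.csv")
  write_traces(rec, tp)
  invisible(c(traces = tp))
}

#' @rdname run_simulate
#' @param traces_path Trace CSV (wide dialect) with schedule sidecar.
#' @export
run_call <- function(traces_path, config = list(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- read_traces(traces_path)
  params <- config_call_params(config)
  bleach <- config$bleach_correction
  if (is.null(bleach)) bleach <- "auto"
  norm <- normalize_recording(rec, params, bleach = bleach)
  calls <- call_recording(norm, params)
  write_calls(calls, file.path(out_dir, "calls.csv"))
  invisible(calls)
}

#' @rdname run_simulate
#' @param calls_path Calls CSV from `run_call`.
#' @param schedule_path Schedule CSV (for compound panel and doses).
#' @export
run_analyze <- function(calls_path, schedule_path, config = list(),
                        out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- read_calls(calls_path)
  sched <- read_schedule(schedule_path)
  via <- config$viability_compound
  if (is.null(via)) via <- "ATP"
  profiles <- build_profiles(calls, viability_compound = via)
  tastants <- setdiff(unique(sched$compound[sched$role == "test"]), via)
  freq <- frequency_table(profiles, tastants, viability_compound = via)
  utils::write.csv(freq, file.path(out_dir, "frequencies.csv"),
                   row.names = FALSE, quote = FALSE)
  venns <- list()
  if (length(tastants) >= 2) {
    prs <- utils::combn(tastants, 2, simplify = FALSE)
    venns <- lapply(prs, function(p) {
      v <- venn_counts(profiles, p[1], p[2])
      data.frame(compound_a = p[1], compound_b = p[2], only_a = v$only_a,
                 only_b = v$only_b, both = v$both, total = v$total,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, venns), file.path(out_dir, "venn.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  delays <- lapply(stats::setNames(nm = c(via, tastants)), function(cmp)
    onset_delay_summary(calls, cmp))
  summary <- list(
    n_cells = length(unique(calls$cell_id)),
    viability_compound = via,
    frequencies = freq,
    onset_delays = delays)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(summary)
}
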