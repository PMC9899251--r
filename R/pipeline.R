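#' Read a trace sidecar configuration
#'
#' A trace CSV travels with a JSON sidecar giving the irradiation window
#' and, optionally, the analysis windows and guard:
#' ```json
#' {"irradiation_start": 120, "irradiation_end": 120.6,
#'  "guard_s": 2, "window_s": 60,
#'  "pre_window": [60, 120], "post_window": [122.6, 182.6]}
#' ```
#' Only the irradiation window is mandatory.
#'
#' @param path JSON file path.
#' @return Named list of analysis settings.
#' @export
read_trace_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$irradiation_start) || is.null(cfg$irradiation_end))
    stop(sprintf("trace config '%s' must give irradiation_start/end", path),
         call. = FALSE)
  cfg
}

#' Run the calorimeter analysis pipeline over a set of traces
#'
#' Reads every trace, applies the drift analysis and correction chain,
#' and aggregates the per-run doses into a mean with its Type A relative
#' standard error. The report records every constant used (specific-heat
#' model, correction factors, windows), so it is self-describing.
#'
#' @param config A named list (or path to a JSON file holding one) with:
#'   `trace_files` (character vector of CSVs) or `trace_dir` (directory
#'   scanned for `*.csv`); `trace_config` (path to the shared sidecar
#'   JSON, see [read_trace_config()]) or inline `irradiation_start` /
#'   `irradiation_end` plus optional `guard_s`, `window_s`,
#'   `pre_window`, `post_window`; optional `factors` (named list
#'   overriding [correction_factors()] defaults); optional `out` (path
#'   for the JSON report).
#' @return Report list (invisibly written to `config$out` when set):
#'   per-run records with `delta_T`, `T_eval`, `dose_to_core`,
#'   `dose_to_water` and fit diagnostics, plus the aggregate.
#' @export
run_calorimeter_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  files <- config$trace_files
  if (is.null(files) && !is.null(config$trace_dir))
    files <- list.files(config$trace_dir, pattern = "\\.csv$",
                        full.names = TRUE)
  if (is.null(files) || length(files) == 0L)
    stop("no trace files to analyse", call. = FALSE)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L)
    stop(sprintf("trace files not found: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  tc <- if (!is.null(config$trace_config)) read_trace_config(config$trace_config)
        else config
  if (is.null(tc$irradiation_start) || is.null(tc$irradiation_end))
    stop("config must give irradiation_start/end (inline or via trace_config)",
         call. = FALSE)
  factors <- if (is.null(config$factors)) correction_factors()
             else do.call(correction_factors, as.list(config$factors))
  heat_model <- specific_heat_model()
  guard_s <- if (is.null(tc$guard_s)) 2 else tc$guard_s
  window_s <- if (is.null(tc$window_s)) 60 else tc$window_s
  runs <- lapply(files, function(f) {
    tr <- read_trace_csv(f, tc$irradiation_start, tc$irradiation_end)
    res <- analyze_calorimeter_run(
      tr, factors = factors, heat_model = heat_model,
      pre_window = tc$pre_window, post_window = tc$post_window,
      guard_s = guard_s, window_s = window_s)
    list(file = basename(f),
         delta_T_K = res$delta_T, T_eval_K = res$T_eval,
         dose_to_core_gy = res$dose_to_core,
         dose_to_water_gy = res$dose_to_water,
         pre_fit_rms_K = res$rise$pre_fit$rms,
         post_fit_rms_K = res$rise$post_fit$rms,
         flagged = res$rise$flagged)
  })
  doses <- vapply(runs, `[[`, 0, "dose_to_water_gy")
  agg <- if (length(doses) >= 2L) aggregate_runs(doses)
         else list(mean = mean(doses), sd = NA_real_, rel_se_pct = NA_real_,
                   n = length(doses))
  report <- list(
    schema_version = 1L,
    constants = list(
      specific_heat = unclass(heat_model),
      correction_factors = unclass(factors),
      guard_s = guard_s, window_s = window_s,
      irradiation_start = tc$irradiation_start,
      irradiation_end = tc$irradiation_end),
    runs = runs,
    aggregate = agg)
  if (!is.null(config$out))
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}

#' Compare calorimeter and chamber doses per field
#'
#' Matches two dose tables by field label and reports the per-field
#' ratio `D_cal / D_chamber` together with the mean ratio and its Type A
#' standard error across fields (the dashed-line summary of a
#' calorimeter-vs-chamber benchmark). Field labels are free strings; the
#' usual convention names each field after its size rounded down to the
#' nearest integer (e.g. `"12x5"`).
#'
#' @param calorimeter,chamber Data frames with columns `field` and
#'   `dose_gy`. Field sets must match exactly.
#' @param out Optional path for a JSON report.
#' @return List with `fields` (data frame of per-field ratios),
#'   `mean_ratio` and `se_ratio` (`NA` with a single field).
#' @export
run_comparison <- function(calorimeter, chamber, out = NULL) {
  need <- c("field", "dose_gy")
  if (!all(need %in% names(calorimeter)) || !all(need %in% names(chamber)))
    stop("dose tables need columns `field` and `dose_gy`", call. = FALSE)
  if (!setequal(calorimeter$field, chamber$field) ||
      anyDuplicated(calorimeter$field) || anyDuplicated(chamber$field))
    stop("field labels do not reconcile between the two dose tables",
         call. = FALSE)
  m <- merge(calorimeter, chamber, by = "field",
             suffixes = c("_cal", "_chamber"))
  m$ratio <- ratio_to_calorimeter(m$dose_gy_cal, m$dose_gy_chamber)
  n <- nrow(m)
  se <- if (n >= 2L) stats::sd(m$ratio) / sqrt(n) else NA_real_
  report <- list(schema_version = 1L, fields = m,
                 mean_ratio = mean(m$ratio), se_ratio = se, n_fields = n)
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}

#' JSON report for one analysed calorimeter run
#'
#' @param result A `"calorimeter_run"` from [analyze_calorimeter_run()].
#' @param path Output path.
#' @export
write_run_report <- function(result, path) {
  stopifnot(inherits(result, "calorimeter_run"))
  rep <- list(
    schema_version = 1L,
    delta_T_K = result$delta_T, T_eval_K = result$T_eval,
    dose_to_core_gy = result$dose_to_core,
    dose_to_water_gy = result$dose_to_water,
    correction_factors = unclass(result$factors),
    diagnostics = list(
      eval_time_s = result$rise$eval_time,
      pre_window = result$rise$pre_fit$window,
      post_window = result$rise$post_fit$window,
      pre_fit_rms_K = result$rise$pre_fit$rms,
      post_fit_rms_K = result$rise$post_fit$rms,
      flagged = result$rise$flagged))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}
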