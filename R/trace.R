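#' Sampled core-temperature record of one calorimeter run
#'
#' Container for a single quasi-adiabatic calorimeter run: the core
#' temperature sampled at a nominal rate (5 Hz for the NPL instrument)
#' together with the known irradiation window. All downstream drift-curve
#' analysis operates on this object.
#'
#' @param times Numeric vector, seconds from run start; strictly increasing.
#' @param temperatures Numeric vector, kelvin; same length as `times`.
#'   Values must lie in (250, 350) K, a sanity bound for a
#'   temperature-stabilised graphite core near room temperature.
#' @param irradiation_start,irradiation_end Seconds; the beam-on window.
#'   Must satisfy `irradiation_start < irradiation_end` and lie inside the
#'   sampled interval.
#' @param sample_rate Nominal sampling rate in Hz (default 5).
#'
#' @return An object of class `"temperature_trace"`.
#' @seealso [fit_drift()], [extract_temperature_rise()],
#'   [analyze_calorimeter_run()], [gen_calorimeter_trace()]
#' @export
#' @examples
#' t <- seq(0, 240, by = 0.2)
#' tr <- temperature_trace(t, 297.7 + 1e-5 * t,
#'                         irradiation_start = 120, irradiation_end = 120.6)
#' tr
temperature_trace <- function(times, temperatures,
                              irradiation_start, irradiation_end,
                              sample_rate = 5) {
  times <- as.numeric(times)
  temperatures <- as.numeric(temperatures)
  if (length(times) != length(temperatures))
    stop("`times` and `temperatures` must have the same length", call. = FALSE)
  if (length(times) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (anyNA(times) || anyNA(temperatures))
    stop("trace contains missing values", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(temperatures <= 250 | temperatures >= 350))
    stop("temperatures outside the (250, 350) K sanity bound", call. = FALSE)
  if (!is.finite(irradiation_start) || !is.finite(irradiation_end) ||
      irradiation_start >= irradiation_end)
    stop("`irradiation_start` must be < `irradiation_end`", call. = FALSE)
  if (irradiation_start < times[1L] || irradiation_end > times[length(times)])
    stop("irradiation window must lie inside the sampled interval",
         call. = FALSE)
  structure(
    list(times = times, temperatures = temperatures,
         irradiation_start = irradiation_start,
         irradiation_end = irradiation_end,
         sample_rate = sample_rate),
    class = "temperature_trace"
  )
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf(
    "<temperature_trace> %d samples @ %g Hz, t = [%g, %g] s\n",
    length(x$times), x$sample_rate, x$times[1L], x$times[length(x$times)]))
  cat(sprintf("  irradiation: [%g, %g] s; T range [%.4f, %.4f] K\n",
              x$irradiation_start, x$irradiation_end,
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Read / write a temperature trace as CSV
#'
#' The on-disk dialect is a plain CSV with header `time_s,temperature_K`
#' ('.' decimal separator, ',' field separator, UTF-8). The irradiation
#' window travels in a sidecar JSON configuration (see
#' [read_trace_config()]) or is passed explicitly.
#'
#' @param path File path.
#' @param irradiation_start,irradiation_end Beam-on window in seconds.
#' @param sample_rate Nominal sampling rate in Hz.
#' @return `read_trace_csv()` returns a [temperature_trace()];
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path, irradiation_start, irradiation_end,
                           sample_rate = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "temperature_K")
  if (!all(need %in% names(df)))
    stop(sprintf("trace file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  temperature_trace(df$time_s, df$temperature_K,
                    irradiation_start, irradiation_end, sample_rate)
}

#' @rdname read_trace_csv
#' @param trace A [temperature_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  utils::write.csv(
    data.frame(time_s = trace$times, temperature_K = trace$temperatures),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
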