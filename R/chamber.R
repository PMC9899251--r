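#' Ionisation chamber specification
#'
#' Calibration metadata for one reference-class ionisation chamber.
#' Reference conditions are resolved from the calibrating laboratory:
#' 293.2 K for NPL-issued and 295.2 K for NIST-issued calibrations, both
#' at 1013.3 mbar.
#'
#' @param name Chamber identifier.
#' @param geometry `"plane-parallel"` or `"cylindrical"`.
#' @param volume_cm3 Sensitive volume, cm^3.
#' @param spacing_mm Electrode spacing, mm (`NA` for cylindrical).
#' @param n_dw Absorbed-dose-to-water calibration coefficient, Gy/C.
#' @param k_q Beam-quality correction factor (Co-60 to the user beam).
#' @param calibration_lab `"NPL"` or `"NIST"`; sets the reference
#'   temperature unless `reference_temperature_K` is given.
#' @param reference_temperature_K,reference_pressure_mbar Reference
#'   conditions of the calibration certificate.
#' @param operating_voltage_V Signed polarising voltage, V (default
#'   -400 V, collecting negative charge).
#' @return Object of class `"chamber_spec"`.
#' @export
chamber_spec <- function(name,
                         geometry = c("plane-parallel", "cylindrical"),
                         volume_cm3, spacing_mm = NA_real_,
                         n_dw, k_q = 1,
                         calibration_lab = c("NPL", "NIST"),
                         reference_temperature_K = NULL,
                         reference_pressure_mbar = 1013.3,
                         operating_voltage_V = -400) {
  geometry <- match.arg(geometry)
  calibration_lab <- match.arg(calibration_lab)
  if (is.null(reference_temperature_K))
    reference_temperature_K <- if (calibration_lab == "NPL") 293.2 else 295.2
  if (volume_cm3 <= 0 || n_dw <= 0 || k_q <= 0)
    stop("volume, N_Dw and k_Q must be positive", call. = FALSE)
  if (!is.na(spacing_mm) && spacing_mm <= 0)
    stop("electrode spacing must be positive", call. = FALSE)
  if (reference_pressure_mbar <= 800 || reference_pressure_mbar >= 1100)
    stop("reference pressure outside (800, 1100) mbar", call. = FALSE)
  structure(
    list(name = name, geometry = geometry, volume_cm3 = volume_cm3,
         spacing_mm = spacing_mm, n_dw = n_dw, k_q = k_q,
         calibration_lab = calibration_lab,
         reference_temperature_K = reference_temperature_K,
         reference_pressure_mbar = reference_pressure_mbar,
         operating_voltage_V = operating_voltage_V),
    class = "chamber_spec"
  )
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf(
    "<chamber_spec> %s (%s, %.3g cm^3), %s-calibrated, ref %.1f K / %.1f mbar\n",
    x$name, x$geometry, x$volume_cm3, x$calibration_lab,
    x$reference_temperature_K, x$reference_pressure_mbar))
  invisible(x)
}

#' One corrected charge measurement
#'
#' @param charge_C Collected charge, coulomb (signed).
#' @param voltage_V Polarising voltage, V (signed; sign encodes the
#'   collecting polarity).
#' @param temperature_K,pressure_mbar Ambient conditions at measurement.
#' @param k_elec Electrometer correction (default 1).
#' @return Object of class `"chamber_reading"`.
#' @export
chamber_reading <- function(charge_C, voltage_V, temperature_K,
                            pressure_mbar, k_elec = 1) {
  if (voltage_V == 0) stop("|voltage| must be > 0", call. = FALSE)
  if (temperature_K <= 0 || pressure_mbar <= 0)
    stop("ambient temperature and pressure must be positive", call. = FALSE)
  if (k_elec <= 0) stop("electrometer correction must be positive",
                        call. = FALSE)
  structure(
    list(charge_C = charge_C, voltage_V = voltage_V,
         temperature_K = temperature_K, pressure_mbar = pressure_mbar,
         k_elec = k_elec),
    class = "chamber_reading"
  )
}

#' Air-density (temperature-pressure) correction
#'
#' `k_TP = (T / T_ref) * (P_ref / P)`, referring the chamber's air mass
#' to the calibration reference conditions.
#'
#' @param temperature_K,pressure_mbar Ambient conditions; a
#'   [chamber_reading()] may be given as `temperature_K` in which case
#'   both are taken from it.
#' @param spec A [chamber_spec()] providing the reference conditions, or
#'   `NULL` to use `reference_temperature_K` / `reference_pressure_mbar`.
#' @param reference_temperature_K,reference_pressure_mbar Used when
#'   `spec` is `NULL` (defaults: NPL conditions, 293.2 K / 1013.3 mbar).
#' @export
#' @examples
#' k_tp(295.2, 1013.3)   # NPL reference: 1.00682
k_tp <- function(temperature_K, pressure_mbar = NULL, spec = NULL,
                 reference_temperature_K = 293.2,
                 reference_pressure_mbar = 1013.3) {
  if (inherits(temperature_K, "chamber_reading")) {
    pressure_mbar <- temperature_K$pressure_mbar
    temperature_K <- temperature_K$temperature_K
  }
  if (!is.null(spec)) {
    reference_temperature_K <- spec$reference_temperature_K
    reference_pressure_mbar <- spec$reference_pressure_mbar
  }
  if (any(temperature_K <= 0) || any(pressure_mbar <= 0))
    stop("temperature and pressure must be positive", call. = FALSE)
  (temperature_K / reference_temperature_K) *
    (reference_pressure_mbar / pressure_mbar)
}

#' Polarity correction factor
#'
#' `k_pol = (|M+| + |M-|) / (2 |M_operating|)` where `M_operating` is the
#' reading at the routinely used polarity.
#'
#' @param m_plus,m_minus Readings at positive and negative polarity.
#' @param m_operating Reading at the operating polarity.
#' @export
k_polarity <- function(m_plus, m_minus, m_operating) {
  if (any(m_operating == 0)) stop("operating reading must be non-zero",
                                  call. = FALSE)
  (abs(m_plus) + abs(m_minus)) / (2 * abs(m_operating))
}

#' Absorbed dose-to-water from an ionisation-chamber reading
#'
#' The reference-dosimetry chain
#' `D_w = |M| * k_TP * k_elec * k_pol * k_ion * N_Dw * k_Q`,
#' with the reading corrected to the calibration reference conditions.
#' All corrections are multiplicative, so their order is immaterial.
#'
#' @param reading A [chamber_reading()].
#' @param spec A [chamber_spec()] supplying `N_Dw`, `k_Q` and the
#'   reference conditions.
#' @param k_ion Ion-recombination correction (a number or a
#'   `"recombination_estimate"`).
#' @param k_pol Polarity correction.
#' @return Dose in Gy.
#' @export
dose_from_chamber <- function(reading, spec, k_ion = 1, k_pol = 1) {
  stopifnot(inherits(reading, "chamber_reading"),
            inherits(spec, "chamber_spec"))
  if (inherits(k_ion, "recombination_estimate")) k_ion <- k_ion$k_ion
  if (k_ion <= 0 || k_pol <= 0)
    stop("corrections must be positive", call. = FALSE)
  if (!is.finite(spec$n_dw))
    stop("chamber has no usable calibration coefficient", call. = FALSE)
  abs(reading$charge_C) * k_tp(reading, spec = spec) * reading$k_elec *
    k_pol * k_ion * spec$n_dw * spec$k_q
}

#' Ratio of calorimeter dose to chamber dose
#'
#' Benchmarks chamber-derived doses against the primary standard;
#' vectorised over fields.
#'
#' @param d_cal,d_chamber Doses in Gy, both positive, equal length.
#' @return Numeric vector of ratios `d_cal / d_chamber`.
#' @seealso [run_comparison()] for per-field aggregation with Type A
#'   standard errors.
#' @export
ratio_to_calorimeter <- function(d_cal, d_chamber) {
  if (any(d_cal <= 0)) stop("calorimeter doses must be positive",
                            call. = FALSE)
  if (any(d_chamber <= 0)) stop("chamber doses must be positive",
                                call. = FALSE)
  d_cal / d_chamber
}

#' Load a chamber registry from a JSON file
#'
#' Reads a list of [chamber_spec()] entries; the packaged registry
#' (`system.file("extdata", "chambers.json", package = "flashcal")`)
#' lists the five chambers used in the benchmark with placeholder
#' (non-physical) calibration coefficients flagged `placeholder: true` --
#' real coefficients come from the calibrating laboratory's certificate.
#'
#' @param path JSON file path.
#' @return Named list of `"chamber_spec"` objects.
#' @export
read_chamber_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(x) {
    sp <- chamber_spec(
      name = x$name, geometry = x$geometry, volume_cm3 = x$volume_cm3,
      spacing_mm = if (is.null(x$spacing_mm)) NA_real_ else x$spacing_mm,
      n_dw = x$n_dw_gy_per_c, k_q = x$k_q,
      calibration_lab = x$calibration_lab,
      operating_voltage_V = if (is.null(x$operating_voltage_V)) -400
                            else x$operating_voltage_V)
    attr(sp, "placeholder") <- isTRUE(x$placeholder)
    sp
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
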