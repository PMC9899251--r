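#' Chamber reading versus polarising voltage
#'
#' A saturation curve: mean chamber reading (arbitrary charge units) at a
#' set of distinct positive voltage magnitudes, optionally with the
#' standard deviation of repeats. Input to the Jaffe-plot classifier and
#' the recombination estimators.
#'
#' @param voltage_V Positive, distinct voltage magnitudes.
#' @param reading Positive mean readings, same length.
#' @param reading_sd Optional per-point SD of repeats.
#' @param normalized Logical flag; set by [normalize_saturation()].
#' @return Object of class `"saturation_curve"` (a data frame with
#'   columns `voltage_V`, `reading`, `reading_sd`).
#' @export
saturation_curve <- function(voltage_V, reading, reading_sd = NA_real_,
                             normalized = FALSE) {
  if (length(voltage_V) < 1L) stop("empty curve", call. = FALSE)
  if (length(reading) != length(voltage_V))
    stop("`voltage_V` and `reading` lengths differ", call. = FALSE)
  if (any(voltage_V <= 0)) stop("voltages must be positive", call. = FALSE)
  if (anyDuplicated(voltage_V)) stop("voltages must be distinct", call. = FALSE)
  if (any(reading <= 0)) stop("readings must be positive", call. = FALSE)
  o <- order(voltage_V)
  df <- data.frame(voltage_V = voltage_V[o], reading = reading[o],
                   reading_sd = rep_len(reading_sd, length(voltage_V))[o])
  structure(df, class = c("saturation_curve", "data.frame"),
            normalized = normalized)
}

#' Normalise a saturation curve to its maximum-voltage reading
#'
#' Divides every reading (and SD) by the mean reading at the largest
#' voltage magnitude, so the curve equals 1 there. Idempotent.
#'
#' @param curve A [saturation_curve()].
#' @export
normalize_saturation <- function(curve) {
  stopifnot(inherits(curve, "saturation_curve"))
  ref <- curve$reading[which.max(curve$voltage_V)]
  saturation_curve(curve$voltage_V, curve$reading / ref,
                   curve$reading_sd / ref, normalized = TRUE)
}

#' Classify the beam structure from a Jaffe plot
#'
#' Plots the reciprocal reading against the reciprocal voltage and asks
#' whether the relation is linear (pulsed-beam recombination) or
#' quadratic (continuous-beam recombination). The curve is classed
#' `"continuous"` when adding the quadratic term reduces the residual sum
#' of squares of the linear fit by more than `rss_threshold` (relative)
#' AND the quadratic coefficient is positive; otherwise `"pulsed"`.
#'
#' @param curve A [saturation_curve()] with at least 4 voltage points.
#' @param rss_threshold Relative RSS-improvement threshold (default 0.5).
#' @return Object of class `"jaffe_classification"`: `beam_class`
#'   (`"pulsed"` or `"continuous"`), `rss_linear`, `rss_quadratic`,
#'   `rss_improvement`, and both fitted coefficient vectors (ascending
#'   powers of `1/V`) as diagnostics.
#' @export
jaffe_classify <- function(curve, rss_threshold = 0.5) {
  stopifnot(inherits(curve, "saturation_curve"))
  if (nrow(curve) < 4L)
    stop("Jaffe classification needs at least 4 voltage points",
         call. = FALSE)
  x <- 1 / curve$voltage_V
  y <- 1 / curve$reading
  f1 <- stats::lm.fit(cbind(1, x), y)
  f2 <- stats::lm.fit(cbind(1, x, x^2), y)
  rss1 <- sum(f1$residuals^2)
  rss2 <- sum(f2$residuals^2)
  # a linear fit residual at numerical-roundoff scale already explains
  # the data: pulsed, whatever the (meaningless) relative improvement
  linear_exact <- rss1 <= 1e-20 * sum(y^2)
  impr <- if (rss1 > 0) (rss1 - rss2) / rss1 else 0
  quad_pos <- is.finite(f2$coefficients[3L]) && f2$coefficients[3L] > 0
  structure(
    list(beam_class = if (!linear_exact && impr > rss_threshold && quad_pos)
                        "continuous" else "pulsed",
         rss_linear = rss1, rss_quadratic = rss2, rss_improvement = impr,
         coef_linear = unname(f1$coefficients),
         coef_quadratic = unname(f2$coefficients)),
    class = "jaffe_classification"
  )
}

#' @export
print.jaffe_classification <- function(x, ...) {
  cat(sprintf(
    "<jaffe_classification> %s (RSS improvement %.1f%%, quad coef %.3g)\n",
    x$beam_class, 100 * x$rss_improvement, x$coef_quadratic[3L]))
  invisible(x)
}

new_recombination_estimate <- function(k_ion, method, beam_class,
                                       diagnostics = list(),
                                       flagged = FALSE) {
  structure(
    list(k_ion = k_ion, method = method, beam_class = beam_class,
         diagnostics = diagnostics, flagged = flagged),
    class = "recombination_estimate"
  )
}

#' @export
print.recombination_estimate <- function(x, ...) {
  cat(sprintf("<recombination_estimate> k_ion = %.4f (%s, %s beam)%s\n",
              x$k_ion, x$method, x$beam_class,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Two-voltage recombination correction, continuous beam
#'
#' The quadratic (continuous-beam) two-voltage expression: with
#' `r = V1/V2`, the correction at the operating voltage `V1` is
#' `k_ion = (r^2 - 1) / (r^2 - M1/M2)`.
#' Under pure general recombination, where the collection efficiency is
#' `f(V) = 1 / (1 + xi^2 / V^2)`, this expression is analytically exact.
#' It degrades when initial recombination (a `1/V` term) contributes,
#' which is why it is unreliable for corrections beyond a few percent.
#'
#' @param m1,m2 Readings at `v1` and `v2` (positive).
#' @param v1 Operating voltage magnitude; `v1 > v2 > 0`.
#' @param v2 Reduced voltage magnitude.
#' @return A `"recombination_estimate"`; `flagged` when the reading ratio
#'   sits at or beyond the pole `M1/M2 -> r^2` or when `k_ion < 1`.
#' @export
k_ion_two_voltage_continuous <- function(m1, v1, m2, v2) {
  if (!(v1 > v2 && v2 > 0)) stop("need V1 > V2 > 0", call. = FALSE)
  if (m1 <= 0 || m2 <= 0) stop("readings must be positive", call. = FALSE)
  r2 <- (v1 / v2)^2
  denom <- r2 - m1 / m2
  if (denom <= 0)
    stop("non-physical readings: M1/M2 >= (V1/V2)^2", call. = FALSE)
  k <- (r2 - 1) / denom
  new_recombination_estimate(
    k, method = "two-voltage", beam_class = "continuous",
    diagnostics = list(v1 = v1, v2 = v2, ratio = m1 / m2,
                       pole_distance = denom / r2),
    flagged = k < 1 || denom / r2 < 0.05)
}

#' Three-voltage recombination correction from a saturation curve
#'
#' Fits the reciprocal reading as a quadratic in the reciprocal voltage,
#' `1/M = a + b/V + c/V^2`, through the `n_points` highest voltages of
#' the curve (exact solve for 3 points, least squares for more). The
#' saturated reading is `M_sat = 1/a` and the correction at the operating
#' voltage is `k_ion(V_op) = (a + b/V_op + c/V_op^2) / a`. Fitting at
#' higher voltages keeps the fit where collection efficiency is close to
#' saturation, which is where the quadratic expansion holds.
#'
#' @param curve A [saturation_curve()].
#' @param v_op Operating voltage magnitude; must not exceed the largest
#'   curve voltage.
#' @param n_points Number of highest-voltage points used (>= 3).
#' @return A `"recombination_estimate"` with the fitted coefficients,
#'   `m_sat` and the voltages used in `diagnostics`.
#' @export
k_ion_three_voltage <- function(curve, v_op, n_points = 3L) {
  stopifnot(inherits(curve, "saturation_curve"))
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("`n_points` must be >= 3", call. = FALSE)
  if (nrow(curve) < n_points)
    stop(sprintf("curve has %d points, need >= %d", nrow(curve), n_points),
         call. = FALSE)
  if (v_op <= 0 || v_op > max(curve$voltage_V))
    stop("`v_op` must be positive and not above the largest curve voltage",
         call. = FALSE)
  sel <- utils::tail(order(curve$voltage_V), n_points)
  v <- curve$voltage_V[sel]
  x <- 1 / v
  y <- 1 / curve$reading[sel]
  X <- cbind(1, x, x^2)
  if (abs(det(crossprod(X))) < 1e-300)
    stop("singular system: voltages too close or duplicated", call. = FALSE)
  beta <- unname(stats::lm.fit(X, y)$coefficients)
  a <- beta[1L]
  if (!is.finite(a) || a <= 0)
    stop("non-physical extrapolation: fitted saturated signal <= 0",
         call. = FALSE)
  k <- (a + beta[2L] / v_op + beta[3L] / v_op^2) / a
  new_recombination_estimate(
    k, method = "three-voltage", beam_class = "continuous",
    diagnostics = list(coefficients = beta, m_sat = 1 / a,
                       voltages = sort(v), v_op = v_op),
    flagged = k < 1)
}

#' Read / write a saturation curve as CSV
#'
#' Dialect: header `voltage_V,reading,reading_sd` ('.' decimal, ','
#' separator).
#'
#' @param path File path.
#' @return `read_saturation_csv()` returns a [saturation_curve()].
#' @export
read_saturation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("voltage_V", "reading")
  if (!all(need %in% names(df)))
    stop(sprintf("saturation file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  sd <- if ("reading_sd" %in% names(df)) df$reading_sd else NA_real_
  saturation_curve(df$voltage_V, df$reading, sd)
}

#' @rdname read_saturation_csv
#' @param curve A [saturation_curve()].
#' @export
write_saturation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "saturation_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
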