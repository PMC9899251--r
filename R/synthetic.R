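#' Recipe for a synthetic calorimeter run
#'
#' Defines a generative model for one quasi-adiabatic run: a quadratic
#' pre-irradiation drift around a stabilised baseline (~297.7 K when the
#' jacket is servo-controlled at ~298.2 K), a linear temperature ramp of
#' the true step during the beam-on window, a post-irradiation drift that
#' may change slope as the core relaxes towards the jacket, and additive
#' white Gaussian noise. The true temperature step is back-computed from
#' the target dose-to-water through the same specific-heat and
#' correction-factor chain the analysis applies, so noiseless generation
#' and analysis close exactly.
#'
#' @param baseline_K Core temperature at t = 0, K (default 297.7).
#' @param pre_drift Length-2 numeric `c(slope, quad)` of the
#'   pre-irradiation drift in K s^-1 and K s^-2 (default a gentle
#'   10 uK s^-1 drift with slight curvature).
#' @param post_drift_delta Length-2 `c(slope_change, quad_change)` added
#'   after the irradiation, in the same units; the default slight cooling
#'   mimics heat redistribution towards the jacket.
#' @param dose_gy Target dose-to-water, Gy (default 7.8, the planned
#'   ~8 Gy physical dose of the transmission fields).
#' @param factors,heat_model Correction chain used to back-compute the
#'   true step (defaults: the shipped values).
#' @param irradiation_start_s Beam-on time, s (default 120).
#' @param duration_s Beam-on duration, s; `NULL` (default) draws
#'   uniformly from \[0.4, 0.8\] s, the delivery-time range of the
#'   scanned UHDR fields.
#' @param noise_sd_K Additive white-noise SD, K (default 5e-5; the
#'   sensing chain resolves temperature to better than 1e-4 K).
#' @param run_length_s Total record length, s (default 240).
#' @param sample_rate_hz Sampling rate, Hz (default 5).
#' @return Object of class `"trace_recipe"`.
#' @export
trace_recipe <- function(baseline_K = 297.7,
                         pre_drift = c(1e-5, -1e-8),
                         post_drift_delta = c(-2e-5, 0),
                         dose_gy = 7.8,
                         factors = correction_factors(),
                         heat_model = specific_heat_model(),
                         irradiation_start_s = 120,
                         duration_s = NULL,
                         noise_sd_K = 5e-5,
                         run_length_s = 240,
                         sample_rate_hz = 5) {
  if (noise_sd_K < 0) stop("noise SD must be >= 0", call. = FALSE)
  if (!is.null(duration_s) && (duration_s <= 0 || duration_s >= 10))
    stop("duration must lie in (0, 10) s", call. = FALSE)
  if (dose_gy < 0) stop("target dose must be >= 0", call. = FALSE)
  structure(
    list(baseline_K = baseline_K, pre_drift = pre_drift,
         post_drift_delta = post_drift_delta, dose_gy = dose_gy,
         factors = factors, heat_model = heat_model,
         irradiation_start_s = irradiation_start_s,
         duration_s = duration_s, noise_sd_K = noise_sd_K,
         run_length_s = run_length_s, sample_rate_hz = sample_rate_hz),
    class = "trace_recipe"
  )
}

#' Generate a synthetic calorimeter trace with known ground truth
#'
#' @param recipe A [trace_recipe()].
#' @param seed Optional integer seed; identical recipe + seed give a
#'   byte-identical trace.
#' @return List with `trace` (a [temperature_trace()]) and `truth`, a
#'   list holding the true `delta_T` (K), `T_eval` (K), `dose_to_core`
#'   and `dose_to_water` (Gy) and the drawn `duration_s`.
#' @export
gen_calorimeter_trace <- function(recipe, seed = NULL) {
  stopifnot(inherits(recipe, "trace_recipe"))
  if (!is.null(seed)) set.seed(seed)
  dur <- recipe$duration_s
  if (is.null(dur)) dur <- stats::runif(1, 0.4, 0.8)
  t0 <- recipe$irradiation_start_s
  t1 <- t0 + dur
  tm <- (t0 + t1) / 2
  pre_poly <- function(t) recipe$baseline_K + recipe$pre_drift[1L] * t +
    recipe$pre_drift[2L] * t^2
  # true step from the target dose, via c(T) at the analysis evaluation point
  T_eval <- pre_poly(tm)
  c_eval <- specific_heat(T_eval, recipe$heat_model)
  kprod <- correction_product(recipe$factors)
  delta_T <- recipe$dose_gy / (kprod * c_eval)
  if (recipe$dose_gy > 0 && delta_T <= 0)
    stop("derived true step must be positive", call. = FALSE)
  times <- seq(0, recipe$run_length_s, by = 1 / recipe$sample_rate_hz)
  temp <- pre_poly(times)
  during <- times > t0 & times < t1
  after <- times >= t1
  temp[during] <- temp[during] + delta_T * (times[during] - t0) / dur
  # the post-drift change is anchored at the evaluation midpoint, so the
  # generated truth is exactly what midpoint extrapolation estimates
  temp[after] <- temp[after] + delta_T +
    recipe$post_drift_delta[1L] * (times[after] - tm) +
    recipe$post_drift_delta[2L] * (times[after] - tm)^2
  if (recipe$noise_sd_K > 0)
    temp <- temp + stats::rnorm(length(temp), sd = recipe$noise_sd_K)
  d_core <- recipe$dose_gy / kprod
  list(
    trace = temperature_trace(times, temp, t0, t1,
                              sample_rate = recipe$sample_rate_hz),
    truth = list(delta_T = delta_T, T_eval = T_eval,
                 dose_to_core = d_core, dose_to_water = recipe$dose_gy,
                 duration_s = dur)
  )
}

#' Generate a reproducible series of repeated runs
#'
#' Emulates a repeated-irradiation session: `n_runs` independent traces
#' whose true doses are jittered around the recipe's target with a given
#' relative standard deviation. Per-run seeds are derived from the master
#' seed, so the whole series is reproducible; runs are independent (each
#' irradiation is treated as a full thermal reset).
#'
#' @param recipe A [trace_recipe()].
#' @param n_runs Number of runs (>= 1).
#' @param inter_run_rel_sd Relative SD of the true per-run dose, as a
#'   fraction (0.0018 for 0.18%).
#' @param seed Master seed.
#' @return List of `n_runs` elements, each as returned by
#'   [gen_calorimeter_trace()].
#' @export
gen_run_series <- function(recipe, n_runs, inter_run_rel_sd = 0,
                           seed = NULL) {
  stopifnot(inherits(recipe, "trace_recipe"))
  if (n_runs < 1L) stop("`n_runs` must be >= 1", call. = FALSE)
  if (inter_run_rel_sd < 0) stop("relative SD must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  jitter <- if (inter_run_rel_sd > 0)
    stats::rnorm(n_runs, mean = 1, sd = inter_run_rel_sd) else rep(1, n_runs)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  lapply(seq_len(n_runs), function(i) {
    r <- recipe
    r$dose_gy <- recipe$dose_gy * jitter[i]
    gen_calorimeter_trace(r, seed = run_seeds[i])
  })
}

#' Recipe for a synthetic chamber saturation curve
#'
#' Generative collection-efficiency model
#' `M(V) = M_sat * [1/(1 + A/V)] * [1/(1 + xi^2/V^2)] * (1 + m*V) * (1 + eps)`
#' combining initial recombination (the `A/V` term), general
#' recombination for a continuous beam (the `xi^2/V^2` term), an optional
#' charge-multiplication term growing linearly with voltage (`m*V`,
#' default off -- present in real small-gap chambers at high voltage but
#' never corrected for by the estimators), and multiplicative Gaussian
#' noise `eps`. The true correction is
#' `k_ion(V) = (1 + A/V) * (1 + xi^2/V^2)` (multiplication excluded, as
#' it is a signal excess, not a collection loss).
#'
#' @param m_sat Saturated reading (arbitrary charge units).
#' @param xi2 General-recombination parameter, V^2 (>= 0).
#' @param A Initial-recombination parameter, V (>= 0, default 0).
#' @param multiplication Charge-multiplication coefficient per volt
#'   (default 0).
#' @param voltages_V Positive distinct voltage magnitudes (default a
#'   50-600 V ladder in 50 V steps; measured saturation curves extend
#'   well above the 400 V operating voltage, which is what makes a fit
#'   at higher voltages possible).
#' @param rel_noise_sd Relative noise SD (fraction, default 0).
#' @return Object of class `"curve_recipe"`.
#' @seealso [xi2_for_k_ion()] to pick `xi2` from a target correction.
#' @export
curve_recipe <- function(m_sat = 1, xi2 = 0, A = 0, multiplication = 0,
                         voltages_V = seq(50, 600, by = 50),
                         rel_noise_sd = 0) {
  if (m_sat <= 0) stop("saturated reading must be positive", call. = FALSE)
  if (xi2 < 0 || A < 0 || multiplication < 0 || rel_noise_sd < 0)
    stop("model parameters must be >= 0", call. = FALSE)
  if (any(voltages_V <= 0) || anyDuplicated(voltages_V))
    stop("voltages must be positive and distinct", call. = FALSE)
  structure(
    list(m_sat = m_sat, xi2 = xi2, A = A, multiplication = multiplication,
         voltages_V = voltages_V, rel_noise_sd = rel_noise_sd),
    class = "curve_recipe"
  )
}

#' General-recombination parameter for a target correction
#'
#' Inverts `k = 1 + xi^2/V^2`: returns `xi2 = (k - 1) * V^2`, the
#' parameter that makes the pure general-recombination model have
#' correction `k_ion_target` at voltage `v`.
#'
#' @param k_ion_target Target correction (>= 1).
#' @param v Voltage magnitude, V.
#' @export
xi2_for_k_ion <- function(k_ion_target, v) {
  if (any(k_ion_target < 1)) stop("target k_ion must be >= 1", call. = FALSE)
  (k_ion_target - 1) * v^2
}

#' Generate a synthetic saturation curve with its true correction
#'
#' @param recipe A [curve_recipe()].
#' @param seed Optional seed for the noise draw.
#' @return List with `curve` (a [saturation_curve()]) and `k_ion_true`,
#'   a function of voltage returning the true correction
#'   `(1 + A/V)(1 + xi^2/V^2)`.
#' @export
gen_saturation_curve <- function(recipe, seed = NULL) {
  stopifnot(inherits(recipe, "curve_recipe"))
  if (!is.null(seed)) set.seed(seed)
  v <- recipe$voltages_V
  f <- 1 / ((1 + recipe$A / v) * (1 + recipe$xi2 / v^2))
  reading <- recipe$m_sat * f * (1 + recipe$multiplication * v)
  if (recipe$rel_noise_sd > 0)
    reading <- reading *
      (1 + stats::rnorm(length(v), sd = recipe$rel_noise_sd))
  list(
    curve = saturation_curve(v, reading,
                             reading_sd = recipe$m_sat * recipe$rel_noise_sd),
    k_ion_true = function(V) (1 + recipe$A / V) * (1 + recipe$xi2 / V^2)
  )
}
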