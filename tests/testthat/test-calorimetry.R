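test_that("quadratic drift fit recovers exact polynomial coefficients", {
  t <- seq(0, 240, by = 0.2)
  temp <- 297.7 + 1e-4 * t - 2e-7 * t^2
  tr <- temperature_trace(t, temp, 230, 230.5)
  m <- fit_drift(tr, c(0, 100))
  expect_equal(drift_coefficients(m, origin = 0),
               c(297.7, 1e-4, -2e-7), tolerance = 1e-10)
  expect_lt(m$rms, 1e-10)

  # constant trace: (297.700, 0, 0), zero residual
  tr2 <- temperature_trace(t, rep(297.700, length(t)), 230, 230.5)
  m2 <- fit_drift(tr2, c(0, 100))
  expect_equal(drift_coefficients(m2, origin = 0), c(297.700, 0, 0),
               tolerance = 1e-12)
  expect_equal(m2$rms, 0, tolerance = 1e-12)

  # refitting on the model's own predictions is a fixed point
  pred <- predict(m, t)
  tr3 <- temperature_trace(t, pred, 230, 230.5)
  m3 <- fit_drift(tr3, c(0, 100))
  expect_equal(m3$coefficients, m$coefficients, tolerance = 1e-9)
})

test_that("drift fit agrees with an independent normal-equations solver", {
  set.seed(42)
  t <- seq(0, 119.8, by = 0.2)            # 600 samples of pre-drift
  truth <- c(297.7, 1e-5, -1e-8)
  y <- truth[1] + truth[2] * t + truth[3] * t^2 +
    rnorm(length(t), sd = 5e-5)
  tr <- temperature_trace(c(t, 120.2, 120.4, 121:180),
                          c(y, rep(297.71, 62)), 119.9, 120.1)
  m <- fit_drift(tr, c(0, 119.8))
  oracle <- normal_equations_quadratic(t, y)
  expect_equal(drift_coefficients(m, origin = 0), unname(oracle$beta),
               tolerance = 1e-8)
  # recovered constant term within 3 standard errors of truth
  expect_lt(abs(oracle$beta[1] - truth[1]), 3 * oracle$se[1])
})

test_that("drift fit rejects degenerate and overlapping windows", {
  tr <- make_poly_trace()
  expect_error(fit_drift(tr, c(0, 0.4)), "degenerate")
  expect_error(fit_drift(tr, c(119, 121)), "overlaps")
  # touching the irradiation boundary is allowed
  expect_s3_class(fit_drift(tr, c(60, 120)), "drift_model")
})

test_that("temperature rise equals the constructed step for noiseless traces", {
  # flat 297.700 before, flat 297.710 after: exactly 10 mK
  tr <- make_poly_trace(baseline = 297.700, step = 0.010)
  rise <- extract_temperature_rise(tr)
  expect_equal(rise$delta_T, 0.010, tolerance = 1e-10)

  # identical linear drift 1 uK/s on both sides, 9.92 mK step,
  # independent of eval_time
  tr2 <- make_poly_trace(pre = c(1e-6, 0), step = 9.92e-3)
  r0 <- extract_temperature_rise(tr2)
  expect_equal(r0$delta_T, 9.92e-3, tolerance = 1e-10)
  for (et in c(119, 120.3, 121.5)) {
    r <- extract_temperature_rise(tr2, eval_time = et)
    expect_equal(r$delta_T, 9.92e-3, tolerance = 1e-10)
  }

  # quadratic drifts plus slope change: still exact (property loop)
  for (i in 1:5) {
    set.seed(i)
    step <- runif(1, 5e-3, 15e-3)
    tr3 <- make_poly_trace(pre = c(runif(1, -2e-5, 2e-5),
                                   runif(1, -2e-8, 2e-8)),
                           post_delta = c(runif(1, -3e-5, 0), 0),
                           step = step)
    expect_equal(extract_temperature_rise(tr3)$delta_T, step,
                 tolerance = 1e-10)
  }
})

test_that("temperature-rise extraction is unbiased under sensing noise", {
  # 200 seeds at 100 uK white noise: mean recovery within 2 SE of truth
  recipe <- trace_recipe(noise_sd_K = 1e-4, duration_s = 0.6)
  errs <- vapply(1:200, function(s) {
    g <- gen_calorimeter_trace(recipe, seed = s)
    extract_temperature_rise(g$trace)$delta_T - g$truth$delta_T
  }, 0)
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(length(errs)))
})

test_that("a cooling run yields a flagged non-positive rise, not an error", {
  tr <- make_poly_trace(step = -2e-3)
  expect_warning(rise <- extract_temperature_rise(tr), "non-positive")
  expect_true(rise$flagged)
  expect_lt(rise$delta_T, 0)
})

test_that("specific heat follows the linear graphite model", {
  expect_equal(specific_heat(273.15), 651.57)
  expect_equal(specific_heat(297.70), 718.837)
  expect_equal(specific_heat(274.15), 654.31)
  expect_error(specific_heat(200), "validity range")
  expect_error(specific_heat(360), "validity range")
})

test_that("dose-to-core is specific heat times temperature rise", {
  expect_equal(dose_to_core(0, 297.7), 0)
  expect_equal(dose_to_core(9.921e-3, 297.7), 718.837 * 9.921e-3)
  expect_equal(dose_to_core(9.921e-3, 297.7), 7.132, tolerance = 1e-4)
  expect_equal(dose_to_core(2 * 9.921e-3, 297.7),
               2 * dose_to_core(9.921e-3, 297.7))
})

test_that("dose-to-water applies the five-factor product", {
  unit <- correction_factors(1, 1, 1, 1, 1)
  expect_equal(dose_to_water(3.14, unit), 3.14)
  expect_equal(correction_product(correction_factors()),
               1.0016 * 1.0029 * 1.1210 * 0.9713 * 1.0000)
  expect_equal(dose_to_water(1), 1.09373, tolerance = 1e-5)
  expect_equal(dose_to_water(7.132), 7.800, tolerance = 1e-3)
  expect_error(correction_factors(k_fl = 0.5), "0.8, 1.3")
})

test_that("source-distance correction is an inverse-square ratio", {
  expect_equal(k_z_distance(200, 200), 1.0000)
  expect_equal(k_z_distance(202, 200), 1.0201)
  expect_equal(k_z_distance(1, 2), 0.25)
  expect_error(k_z_distance(-1, 2), "positive")
})

test_that("run aggregation reports mean, SD and Type A relative SE", {
  a <- aggregate_runs(c(7.8, 7.8, 7.8))
  expect_equal(a$mean, 7.8)
  expect_equal(a$sd, 0)
  expect_equal(a$rel_se_pct, 0)
  b <- aggregate_runs(c(1, 3))
  expect_equal(b$mean, 2)
  expect_equal(b$sd, sqrt(2))
  expect_error(aggregate_runs(7.8), "at least 2")
})

test_that("graphite-equivalent thickness scales linearly", {
  f <- 5.9 / 5.2
  expect_equal(graphite_equivalent_thickness(5.2, f), 5.9)
  expect_equal(graphite_equivalent_thickness(10.4, f), 11.8)
  expect_equal(graphite_equivalent_thickness(3.3, 1), 3.3)
  expect_error(graphite_equivalent_thickness(-1, 1), "positive")
})

test_that("dose chain is scale-equivariant and preserves the factor product", {
  base <- make_poly_trace(step = 9.92e-3)
  r1 <- analyze_calorimeter_run(base)
  for (alpha in c(0.5, 2, 3.7)) {
    tr <- make_poly_trace(step = alpha * 9.92e-3)
    r <- analyze_calorimeter_run(tr)
    expect_equal(r$dose_to_water, alpha * r1$dose_to_water,
                 tolerance = 1e-9)
    # chain identity holds exactly, per run
    expect_identical(r$dose_to_water,
                     r$dose_to_core * correction_product(r$factors))
  }
})
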