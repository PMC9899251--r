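test_that("trace generation is deterministic given recipe and seed", {
  r <- trace_recipe()
  g1 <- gen_calorimeter_trace(r, seed = 123)
  g2 <- gen_calorimeter_trace(r, seed = 123)
  expect_identical(g1$trace$temperatures, g2$trace$temperatures)
  expect_identical(g1$truth, g2$truth)
  g3 <- gen_calorimeter_trace(r, seed = 124)
  expect_false(identical(g1$trace$temperatures, g3$trace$temperatures))
})

test_that("noiseless generated traces close on the recipe truth", {
  # target 7.8 Gy with shipped constants implies a ~9.92 mK step
  r <- trace_recipe(noise_sd_K = 0, duration_s = 0.6,
                    pre_drift = c(0, 0), post_drift_delta = c(0, 0))
  g <- gen_calorimeter_trace(r)
  expect_equal(g$truth$delta_T, 9.92e-3, tolerance = 1e-4)
  expect_equal(diff(range(g$trace$temperatures)), g$truth$delta_T,
               tolerance = 1e-12)
  # full analysis recovers truth to machine precision, drifts or not
  for (i in 1:5) {
    set.seed(i)
    r2 <- trace_recipe(noise_sd_K = 0,
                       pre_drift = c(runif(1, -2e-5, 2e-5),
                                     runif(1, -2e-8, 2e-8)),
                       post_drift_delta = c(runif(1, -3e-5, 0), 0),
                       dose_gy = runif(1, 2, 10))
    g2 <- gen_calorimeter_trace(r2, seed = i)
    res <- analyze_calorimeter_run(g2$trace)
    expect_equal(res$delta_T, g2$truth$delta_T, tolerance = 1e-10)
    expect_equal(res$dose_to_water, g2$truth$dose_to_water,
                 tolerance = 1e-9)
  }
})

test_that("a zero-dose recipe yields a flat noisy trace and ~zero recovered rise", {
  r <- trace_recipe(dose_gy = 0, noise_sd_K = 5e-5, duration_s = 0.6,
                    pre_drift = c(0, 0), post_drift_delta = c(0, 0))
  g <- gen_calorimeter_trace(r, seed = 5)
  rise <- suppressWarnings(extract_temperature_rise(g$trace))
  # recovered step statistically indistinguishable from 0 (~< 4 sigma
  # of the extrapolation noise)
  expect_lt(abs(rise$delta_T), 1e-4)
})

test_that("statistical closure: estimator bias below 0.1% at stated noise", {
  recipe <- trace_recipe()    # 50 uK noise, random 0.4-0.8 s delivery
  rel_err <- vapply(1:200, function(s) {
    g <- gen_calorimeter_trace(recipe, seed = s)
    (analyze_calorimeter_run(g$trace)$dose_to_water -
       g$truth$dose_to_water) / g$truth$dose_to_water
  }, 0)
  expect_lt(abs(mean(rel_err)), 1e-3)
})

test_that("run series are reproducible with controlled inter-run spread", {
  r <- trace_recipe(noise_sd_K = 0, duration_s = 0.6)
  s1 <- gen_run_series(r, 5, inter_run_rel_sd = 0.0018, seed = 77)
  s2 <- gen_run_series(r, 5, inter_run_rel_sd = 0.0018, seed = 77)
  expect_identical(lapply(s1, function(x) x$truth),
                   lapply(s2, function(x) x$truth))
  # zero spread: all truths identical
  s0 <- gen_run_series(r, 4, inter_run_rel_sd = 0, seed = 1)
  doses <- vapply(s0, function(x) x$truth$dose_to_water, 0)
  expect_equal(doses, rep(7.8, 4))
  # non-zero spread: truths scatter at roughly the requested level
  s3 <- gen_run_series(r, 200, inter_run_rel_sd = 0.0018, seed = 2)
  d3 <- vapply(s3, function(x) x$truth$dose_to_water, 0)
  expect_equal(sd(d3) / mean(d3), 0.0018, tolerance = 0.25)
})

test_that("saturation-curve generator matches its stated truth function", {
  # no recombination: constant readings, both estimators return 1
  flat <- gen_saturation_curve(curve_recipe())
  expect_equal(diff(range(flat$curve$reading)), 0)
  expect_equal(k_ion_three_voltage(flat$curve, 400)$k_ion, 1,
               tolerance = 1e-12)
  m1 <- flat$curve$reading[flat$curve$voltage_V == 400]
  m2 <- flat$curve$reading[flat$curve$voltage_V == 200]
  expect_equal(k_ion_two_voltage_continuous(m1, 400, m2, 200)$k_ion, 1)

  # small-gap chamber regime: k_ion(400) = 1.001 -> near-flat curve
  small <- gen_saturation_curve(curve_recipe(xi2 = xi2_for_k_ion(1.001, 400)))
  nrm <- normalize_saturation(small$curve)
  high <- nrm$reading[nrm$voltage_V >= 200]
  expect_true(all(high > 0.99))
  expect_equal(small$k_ion_true(400), 1.001)

  # heavy general recombination: visibly unsaturated at low voltage
  heavy <- gen_saturation_curve(curve_recipe(xi2 = xi2_for_k_ion(1.2, 400)))
  nrm2 <- normalize_saturation(heavy$curve)
  expect_lt(nrm2$reading[nrm2$voltage_V == 50], 0.10)
  expect_equal(heavy$k_ion_true(400), 1.2, tolerance = 1e-12)

  # reading model: M = m_sat / [(1+A/V)(1+xi^2/V^2)], noiseless
  rc <- curve_recipe(m_sat = 2, xi2 = 9000, A = 6)
  g <- gen_saturation_curve(rc)
  v <- g$curve$voltage_V
  expect_equal(g$curve$reading, 2 / ((1 + 6 / v) * (1 + 9000 / v^2)),
               tolerance = 1e-12)
  # determinism under noise
  ga <- gen_saturation_curve(curve_recipe(xi2 = 9000, rel_noise_sd = 1e-3),
                             seed = 9)
  gb <- gen_saturation_curve(curve_recipe(xi2 = 9000, rel_noise_sd = 1e-3),
                             seed = 9)
  expect_identical(ga$curve$reading, gb$curve$reading)
})
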