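make_stream <- function(times, levels, wl = 412) {
  frequency_stream(data.frame(time_s = times, lightLevel = levels,
                              wavelengthLine = wl, lightIntensity = 255))
}

test_that("endpoint delta measures the start-to-end frequency difference", {
  t <- seq(0, 320, by = 0.5)
  flat <- make_stream(t, rep(1000, length(t)))
  expect_equal(endpoint_delta(flat), 0)
  m <- 100 / 60                                    # 100 Hz per minute
  line <- make_stream(t, 5e5 - m * t)
  expect_equal(endpoint_delta(line, window_s = 300, k = 1), 300 * m,
               tolerance = 1e-6)
  expect_error(endpoint_delta(make_stream(1:20, 21:2), window_s = 300),
               "evaluation window")
  # paired twin fixtures: the inhibited stream moves less
  ctrl <- run_assay(ellman_scenario())
  inh <- run_assay(ellman_scenario(inhibitor_mol_L = nmol_per_L(625),
                                   preincubation_s = 420))
  expect_lt(endpoint_delta(inh), endpoint_delta(ctrl))
})

test_that("trimming drops exactly the pre-cut records", {
  t <- seq(0.5, 360, by = 0.5)                      # 2 readings per second
  st <- make_stream(t, 1e5 - 10 * t)
  expect_equal(trim_initial_artifact(st, 0), st)
  trimmed <- trim_initial_artifact(st, 150)
  expect_gte(nrow(trimmed), 420)
  expect_true(all(trimmed$time_s >= 150))
  expect_equal(trimmed$lightLevel, st$lightLevel[st$time_s >= 150])
  expect_error(trim_initial_artifact(st, 400), "no records remain")
})

test_that("kinetic slopes match the closed-form normal equations", {
  t <- seq(1, 300, by = 1)
  line <- make_stream(t, 4e5 - (100 / 60) * t)
  fit <- kinetic_slope(line)
  expect_equal(fit$slope * 60, -100, tolerance = 1e-9)  # -100 Hz per minute
  expect_equal(fit$r2, 1)
  flat <- make_stream(t, rep(500, length(t)))
  expect_equal(kinetic_slope(flat)$slope, 0)
  # random fixture vs normal-equation oracle
  set.seed(20)
  x <- sort(runif(20, 0, 300))
  y <- 3e5 - 40 * x + rnorm(20, 0, 500)
  st <- make_stream(x, y)
  got <- kinetic_slope(st)
  want <- oracle_ols(x, y)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$residual_sd, want$residual_sd, tolerance = 1e-10)
  expect_equal(got$r2, want$r2, tolerance = 1e-10)
  expect_error(kinetic_slope(make_stream(c(1, 2), c(2, 1))), "at least 3")
})

test_that("absorbance conversion inverts the detector model", {
  t <- 1:10
  a_true <- 0.01 * t
  st <- make_stream(t, 3e5 * 10^(-a_true) + 16)
  expect_equal(stream_to_absorbance(st, blank_hz = 3e5 + 16, dark_hz = 16),
               a_true, tolerance = 1e-12)
  expect_error(stream_to_absorbance(st), "blank")
  dark_st <- make_stream(t, rep(10, 10))
  expect_error(stream_to_absorbance(dark_st, blank_hz = 3e5, dark_hz = 16),
               "dark")
})

test_that("Michaelis-Menten fitting recovers exact saturation data", {
  s <- substrate_levels()
  for (km in c(1.16e-4, 9.82e-5)) {
    y <- 2.6e-7 * s / (km + s)
    fit <- fit_michaelis_menten(s, y)
    expect_equal(fit$km, km, tolerance = 1e-6)
    expect_equal(fit$vmax, 2.6e-7, tolerance = 1e-6)
    expect_gt(fit$r2, 1 - 1e-10)
    expect_false(fit$poorly_identified)
  }
  expect_equal(coef(fit_michaelis_menten(s, 1 * s / (1e-4 + s)))[["km"]],
               1e-4, tolerance = 1e-6)
  # noisy data: agree with an independent Levenberg-Marquardt implementation
  set.seed(12)
  y_noisy <- 2.6e-7 * s / (1.16e-4 + s) * (1 + rnorm(7, 0, 0.02))
  ours <- fit_michaelis_menten(s, y_noisy)
  lm_fit <- minpack.lm::nlsLM(y ~ vmax * s / (km + s),
                              data = data.frame(s = s, y = y_noisy),
                              start = list(vmax = max(y_noisy), km = 1e-4))
  expect_equal(ours$km, coef(lm_fit)[["km"]], tolerance = 1e-6)
  expect_equal(ours$vmax, coef(lm_fit)[["vmax"]], tolerance = 1e-6)
})

test_that("linear responses are flagged as a poorly identified saturation fit", {
  s <- substrate_levels()
  fit <- fit_michaelis_menten(s, 1000 * s)          # KM far above max(s)
  expect_true(fit$poorly_identified)
  expect_gte(fit$km, max(s))
  expect_error(fit_michaelis_menten(s, rep(1, length(s))), "degenerate")
  expect_error(fit_michaelis_menten(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("residual activity is the inhibited-to-control signal ratio", {
  expect_equal(as.numeric(residual_activity(5, 5)), 100)
  expect_equal(as.numeric(residual_activity(0, 5)), 0)
  over <- residual_activity(6, 5)
  expect_equal(as.numeric(over), 100)
  expect_true(attr(over, "out_of_range"))
  expect_error(residual_activity(1, 0), "positive")
  # twin fixture: 0.5 umol/L carbofuran for 7 min leaves 10-15% activity
  ctrl <- run_assay(ellman_scenario())
  inh <- run_assay(ellman_scenario(inhibitor_mol_L = umol_per_L(0.5),
                                   preincubation_s = 420))
  s_c <- abs(kinetic_slope(trim_initial_artifact(ctrl),
                           to_absorbance = TRUE, dark_hz = 16)$slope)
  s_i <- abs(kinetic_slope(trim_initial_artifact(inh),
                           to_absorbance = TRUE, dark_hz = 16)$slope)
  pct <- as.numeric(residual_activity(s_i, s_c))
  expect_gte(pct, 10)
  expect_lte(pct, 15)
})

test_that("calibration LOD follows the 3.3-sigma regression formula", {
  concs <- c(0, 1, 2, 3, 4)
  perfect <- inhibitor_calibration(concs, 2 * concs + 1)
  expect_equal(perfect$lod, 0)
  responses <- c(0.0, 1.1, 1.9, 3.2, 3.8)
  cal <- inhibitor_calibration(concs, responses)
  want <- oracle_ols(concs, responses)
  expect_equal(cal$fit$slope, want$slope, tolerance = 1e-10)
  expect_equal(cal$lod, 3.3 * want$residual_sd / abs(want$slope),
               tolerance = 1e-10)
  expect_error(inhibitor_calibration(1:4, 1:4), "5 calibrators")
  expect_error(inhibitor_calibration(concs, rep(1, 5) + 1e-15 * concs),
               "undetectable")
})

test_that("doubling the calibration noise doubles the expected LOD", {
  concs <- 0:7
  set.seed(31)
  lod_at <- function(sigma) {
    mean(replicate(200, {
      inhibitor_calibration(concs, 2 * concs + rnorm(8, 0, sigma))$lod
    }))
  }
  expect_equal(lod_at(0.4) / lod_at(0.2), 2, tolerance = 0.1)
})

test_that("LOD improves with integration depth on matched-seed twin calibrations", {
  # low calibrators keep the activity response near-linear, so the residual
  # scatter is dominated by counting noise rather than curvature
  concs <- nmol_per_L(c(0, 3, 6, 9, 12, 18, 25))
  lod_for <- function(samples) {
    resp <- vapply(seq_along(concs), function(i) {
      sc <- ellman_scenario(
        inhibitor_mol_L = concs[i], preincubation_s = 420,
        observation_s = 60,
        sensor = sensor_config(samples = samples, mode = "stochastic"),
        seed = 7000 + i)
      endpoint_delta(run_assay(sc), window_s = 60)
    }, numeric(1))
    # response inverted so it grows with concentration
    inhibitor_calibration(concs * 1e9, resp[1] - resp)$lod
  }
  expect_lt(lod_for(16000), lod_for(1000))
})

test_that("the plateau optimizer finds the shortest saturating preincubation", {
  flat <- data.frame(time_s = seq(0, 240, 30), residual_activity = 0.12)
  expect_equal(optimize_preincubation(flat), 0)
  prof <- preincubation_profile(umol_per_L(0.5))
  expect_equal(optimize_preincubation(prof), 420)
  # tightening the tolerance never shortens the returned time
  times <- vapply(c(0.05, 0.02, 0.01, 0.005),
                  function(tol) optimize_preincubation(prof, plateau_tol = tol),
                  numeric(1))
  expect_true(all(diff(times) >= 0))
  # a profile still falling at its end never reaches the plateau
  steep <- data.frame(time_s = c(0, 100, 200, 290),
                      residual_activity = c(1, 0.7, 0.4, 0.13))
  expect_error(optimize_preincubation(steep), "closest approach")
})

test_that("endpoint and kinetic regimes agree in the zero-order small-signal limit", {
  sc <- ellman_scenario(ellman = ellman_params(vmax_mol_L_s = 1e-9,
                                               km_mol_L = 1.16e-4,
                                               s0_mol_L = 2e-3))
  st <- run_assay(sc)
  delta <- endpoint_delta(st, window_s = 300)
  slope <- abs(kinetic_slope(st)$slope)
  expect_equal(delta, slope * 300, tolerance = 0.01)
})
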