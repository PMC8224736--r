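test_that("QC flags extreme outliers and extravasated occasions", {
  # the infamous 11,317 mg/L sample
  prof <- concentration_profile("o", 1, "pig", 60, 1500,
                                times = c(5, 10, 180, 240, 300),
                                concentrations = c(11317, 200, 90, 80, 70))
  qc <- qc_screen(prof)
  expect_equal(qc$n_outlier, 1L)
  expect_equal(qc$profile$samples$flag[1], "outlier")
  expect_false(qc$excluded_occasion)

  # maximum at 180 min is illogical after an IV bolus: extravasation
  prof2 <- concentration_profile("x", 1, "goat", 70, 1500,
                                 times = c(5, 10, 180, 240, 300),
                                 concentrations = c(50, 60, 120, 100, 90))
  qc2 <- qc_screen(prof2)
  expect_true(qc2$extravasation)
  expect_true(qc2$excluded_occasion)

  # clean profile with Tmax at the first sample: nothing flagged
  p <- ref_params3()
  clean <- simulate_occasion(p, 1500, default_schedule(), 0, seed = 1)
  qc3 <- qc_screen(clean)
  expect_equal(qc3$n_outlier + qc3$n_blq, 0L)
  expect_false(qc3$excluded_occasion)
})

test_that("QC is idempotent and reports missing terminal data", {
  prof <- concentration_profile("i", 1, "goat", 70, 1500,
                                times = c(5, 10, 20, 30, 60),
                                concentrations = c(300, 250, 200, 170, 120))
  qc1 <- qc_screen(prof)
  expect_true(qc1$insufficient_terminal)
  expect_true(qc1$excluded_occasion)
  qc2 <- qc_screen(qc1$profile)
  expect_equal(qc1[c("n_blq", "n_outlier", "extravasation",
                     "insufficient_terminal", "excluded_occasion")],
               qc2[c("n_blq", "n_outlier", "extravasation",
                     "insufficient_terminal", "excluded_occasion")])
  expect_identical(qc1$profile$samples, qc2$profile$samples)
})

test_that("terminal fit reproduces exact log-linear data and its equivariances", {
  fit <- fit_terminal_slope(exact_mono_profile(C1 = 100, b1 = 0.004))
  expect_equal(fit$C1, 100, tolerance = 1e-12)
  expect_equal(fit$b1, 0.004, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 3L)

  # doubling concentrations doubles C1, leaves b1 unchanged
  p2 <- exact_mono_profile(C1 = 200, b1 = 0.004)
  fit2 <- fit_terminal_slope(p2)
  expect_equal(fit2$C1, 200, tolerance = 1e-12)
  expect_equal(fit2$b1, fit$b1, tolerance = 1e-12)

  # rising terminal concentrations are not an eliminating profile
  bad <- concentration_profile("r", 1, "goat", 70, 1500,
                               times = c(180, 240, 300),
                               concentrations = c(50, 55, 60))
  expect_error(fit_terminal_slope(bad), "non-eliminating")
  short <- concentration_profile("s", 1, "goat", 70, 1500,
                                 times = c(5, 60), concentrations = c(300, 100))
  expect_error(fit_terminal_slope(short), "insufficient-data")
})

test_that("terminal slope is recovered without bias from proportional noise", {
  set.seed(11)
  b1_hat <- replicate(1000, {
    conc <- 100 * exp(-0.004 * c(180, 240, 300)) * (1 + rnorm(3, 0, 0.05))
    prof <- concentration_profile("n", 1, "goat", 70, 1500,
                                  c(180, 240, 300), conc)
    fit_terminal_slope(prof)$b1
  })
  expect_equal(mean(b1_hat), 0.004, tolerance = 0.01)
})

test_that("slope-intercept clearance implements dose * b1 / C1 in mL/min", {
  expect_equal(cl_one_compartment(1500, list(C1 = 150, b1 = 0.002)), 20)
  # dose-proportionality: doubling dose doubles C1, clearance unchanged
  expect_equal(cl_one_compartment(3000, list(C1 = 300, b1 = 0.002)), 20)
  expect_error(cl_one_compartment(1500, list(C1 = -1, b1 = 0.002)), "invalid-fit")
  expect_error(cl_one_compartment(1500, list(C1 = 150, b1 = 0)), "invalid-fit")

  # a true one-compartment animal is estimated exactly
  p <- micro_params(CL = 0.025, V1 = 8)
  prof <- simulate_occasion(p, 1500, default_schedule(), 0, seed = 3)
  cl <- cl_one_compartment(1500, fit_terminal_slope(prof))
  expect_equal(cl, 25, tolerance = 1e-9)
})

test_that("the quadratic correction matches its printed coefficients and bounds", {
  expect_equal(cl_simplified(0), 0)
  expect_equal(cl_simplified(10), 9.71978, tolerance = 1e-9)
  expect_equal(cl_simplified(20), 18.75216, tolerance = 1e-9)
  x <- seq(0, 140, by = 0.5)
  y <- suppressWarnings(cl_simplified(x))
  expect_true(all(y <= x * 1.006348 + 1e-12))
  turnover <- 1.006348 / (2 * 0.003437)
  rising <- x < turnover
  expect_true(all(diff(y[rising]) > 0))
  expect_warning(cl_simplified(60), "calibration range")
  expect_silent(cl_simplified(57))
  expect_error(cl_simplified(-1), "non-negative")
})

test_that("species BSA formulas give the published values", {
  expect_equal(round(body_surface_area("pig", 70), 2), 1.19)
  expect_equal(body_surface_area("pig", 34), 34^0.656 * 734 / 10000)
  expect_equal(body_surface_area("goat", 70), 70^0.62 * 1147.7 / 10000)
  expect_equal(round(body_surface_area("goat", 70), 3), 1.599)
  expect_error(body_surface_area("sheep", 70), "species")
  expect_error(body_surface_area("goat", -1), "positive")
})

test_that("BSA normalization applies the standardized 70-kg constants", {
  expect_equal(normalize_gfr(20, "goat", 70),
               20 / (70^0.62 * 1147.7 / 10000) * 1.43)
  expect_equal(normalize_gfr(20, "goat", 70), 17.89, tolerance = 1e-3)
  # Kelly's formula returns exactly the pig constant at 70 kg
  expect_equal(normalize_gfr(20, "pig", 70), 20 * 1.19 / body_surface_area("pig", 70),
               tolerance = 1e-12)
  expect_equal(normalize_gfr(20, "pig", 70), 20, tolerance = 2e-3)
  expect_equal(normalize_gfr(40, "goat", 55), 2 * normalize_gfr(20, "goat", 55))
})

test_that("multi-compartment kinetics make the slope-intercept method overestimate", {
  spec <- noiseless_spec()
  coh <- simulate_cohort(spec, 2, 2, 1, seed = 17)
  tr <- cohort_truth(coh)
  profs <- cohort_profiles(coh)
  for (i in seq_along(profs)) {
    est <- estimate_clearance(profs[[i]])
    expect_gt(est$cl_1cmt, tr$cl_true[i])
  }
})

test_that("the sparse estimate is deterministic end to end", {
  prof <- cohort_profiles(simulate_cohort(population_spec(), 1, 0, 1, seed = 5))[[1]]
  a <- estimate_clearance(prof)
  b <- estimate_clearance(prof)
  expect_identical(a[c("cl_1cmt", "cl_sm", "bsa", "mgfr_sm")],
                   b[c("cl_1cmt", "cl_sm", "bsa", "mgfr_sm")])
  expect_lte(a$cl_sm, a$cl_1cmt * 1.006348)
})
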