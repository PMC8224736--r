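test_that("one-compartment macro constants follow the closed form", {
  m <- micro_to_macro(micro_params(CL = 0.02, V1 = 10))
  expect_equal(m$rates, 0.002)
  expect_equal(m$amplitudes, 0.1)
  expect_equal(predict_concentration(m, 1500, 0), 150)
  expect_equal(predict_concentration(m, 1500, 300), 150 * exp(-0.6))
})

test_that("macro coefficients satisfy the AUC identity with positive, ordered modes", {
  set.seed(101)
  for (n in 1:3) {
    for (rep in 1:30) {
      p <- random_params(n)
      m <- micro_to_macro(p)
      expect_length(m$rates, n)
      expect_true(all(m$amplitudes > 0))
      expect_true(all(diff(m$rates) < 0))
      expect_equal(sum(m$amplitudes / m$rates), 1 / p$CL, tolerance = 1e-9)
    }
  }
})

test_that("closed-form predictions match numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(202)
  times <- default_schedule()
  for (n in 1:3) {
    for (rep in 1:10) {
      p <- random_params(n)
      pred <- predict_concentration(micro_to_macro(p), 1500, times)
      oracle <- ode_concentrations(p, 1500, times)
      expect_equal(pred, oracle, tolerance = 1e-8)
    }
  }
})

test_that("trapezoid AUC on a dense grid conserves dose/CL", {
  set.seed(303)
  for (n in 1:3) {
    p <- random_params(n)
    m <- micro_to_macro(p)
    tmax <- 50 / min(m$rates)
    grid <- seq(0, tmax, length.out = 20000)
    conc <- predict_concentration(m, 1500, grid)
    auc <- sum(diff(grid) * (head(conc, -1) + tail(conc, -1)) / 2)
    expect_equal(auc, 1500 / p$CL, tolerance = 1e-3)
  }
})

test_that("predictions are linear in dose, decaying, and reject bad input", {
  p <- ref_params3()
  m <- micro_to_macro(p)
  tt <- default_schedule()
  expect_equal(predict_concentration(m, 3000, tt),
               2 * predict_concentration(m, 1500, tt))
  expect_true(all(diff(predict_concentration(m, 1500, tt)) < 0))
  t_far <- 55 / min(m$rates)
  expect_lt(predict_concentration(m, 1500, t_far),
            1e-15 * predict_concentration(m, 1500, 0))
  expect_error(predict_concentration(m, 1500, -1), "non-negative")
  expect_error(predict_concentration(m, -5, 10), "positive")
  expect_error(micro_params(CL = -0.02, V1 = 10), "positive")
  expect_error(micro_params(CL = 0.02, V1 = 10, Q2 = 0.1), "together")
})

test_that("numerically coincident disposition rates are rejected as degenerate", {
  # two identical, almost uncoupled peripheral compartments collapse the
  # slow eigenvalues onto each other
  p <- micro_params(CL = 0.02, V1 = 5, Q2 = 1e-9, V2 = 5, Q3 = 1e-9, V3 = 5)
  expect_error(micro_to_macro(p), "degenerate")
})

test_that("log-concentration becomes linear with slope -lambda_min in the terminal phase", {
  m <- micro_to_macro(ref_params3())
  lam <- m$rates
  slope_at <- function(t) {
    (log(predict_concentration(m, 1500, t + 0.5)) -
       log(predict_concentration(m, 1500, t - 0.5)))
  }
  t1 <- 5 / lam[2]
  t2 <- 20 / lam[2]
  dev1 <- abs(slope_at(t1) + lam[3])
  dev2 <- abs(slope_at(t2) + lam[3])
  expect_lt(dev1, 1e-3)
  expect_lt(dev2, 1e-6)
  expect_lt(dev2, dev1)  # contamination decays monotonically
})

test_that("proportional error model is exact at zero noise and reproducible", {
  p <- ref_params3()
  sched <- default_schedule()
  prof0 <- simulate_occasion(p, 1500, sched, error_sd = 0, seed = 1)
  expect_equal(prof0$samples$conc,
               predict_concentration(micro_to_macro(p), 1500, sched))
  a <- simulate_occasion(p, 1500, sched, error_sd = 0.1, seed = 42)
  b <- simulate_occasion(p, 1500, sched, error_sd = 0.1, seed = 42)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_occasion(p, 1500, sched, error_sd = 0.1, seed = 43)
  expect_false(identical(a$samples$conc, c2$samples$conc))
  expect_error(simulate_occasion(p, 1500, numeric(0), 0.1), "schedule")
})

test_that("Monte-Carlo CV of simulated observations matches the error SD", {
  p <- micro_params(CL = 0.02, V1 = 10)
  obs <- with(list(), {
    set.seed(7)
    replicate(10000,
      simulate_occasion(p, 1500, 60, error_sd = 0.1)$samples$conc)
  })
  cv <- sd(obs) / mean(obs)
  expect_gt(cv, 0.09)
  expect_lt(cv, 0.11)
})

test_that("LLOQ screening flags exactly the sub-LLOQ samples", {
  prof <- concentration_profile("q", 1, "goat", 70, 1500,
                                times = c(60, 120, 1440),
                                concentrations = c(50, 20, 0.5), lloq = 1)
  out <- apply_lloq(prof)
  expect_equal(out$samples$flag, c("ok", "ok", "blq"))
  expect_equal(out$n_blq, 1L)
  clean <- apply_lloq(exact_mono_profile())
  expect_equal(clean$n_blq, 0L)
  # boundary: lloq/2 flagged, exactly-at-lloq retained
  prof2 <- concentration_profile("q", 1, "goat", 70, 1500,
                                 times = c(60, 120), concentrations = c(1, 0.5),
                                 lloq = 1)
  out2 <- apply_lloq(prof2)
  expect_equal(out2$samples$flag, c("ok", "blq"))
})

test_that("healthy-animal 1440-min samples fall below the default LLOQ", {
  spec <- noiseless_spec()
  a <- draw_individual(spec, "goat", "healthy", seed = 9, bodyweight = 70)
  prof <- apply_lloq(a$occasions[[1]])
  s <- prof$samples
  expect_true(all(s$flag[s$time >= 1440] == "blq"))
  expect_true(all(s$flag[s$time < 1440] == "ok"))
})
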