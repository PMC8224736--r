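test_that("noiseless quadratic pairs are recovered to machine precision", {
  x <- seq(8, 56, length.out = 25)
  y <- 1.006348 * x - 0.003437 * x^2
  fits <- fit_candidates(y, x)
  q <- fits$quadratic
  expect_equal(unname(q$coefficients["a"]), 1.006348, tolerance = 1e-9)
  expect_equal(unname(q$coefficients["b"]), 0.003437, tolerance = 1e-9)
  expect_lt(q$rse, 1e-10)
  expect_equal(predict(q, 10), cl_simplified(10), tolerance = 1e-9)
})

test_that("identity data yield unit slope and vanishing curvature", {
  x <- seq(5, 50, length.out = 20)
  fits <- suppressWarnings(fit_candidates(x, x))
  expect_equal(unname(fits$linear_origin$coefficients["slope"]), 1,
               tolerance = 1e-12)
  expect_equal(unname(fits$quadratic$coefficients["b"]), 0, tolerance = 1e-10)
})

test_that("candidate degrees of freedom follow the parameter counts", {
  set.seed(5)
  x <- runif(34, 8, 57)
  y <- (1.006348 * x - 0.003437 * x^2) * (1 + rnorm(34, 0, 0.05))
  fits <- fit_candidates(y, x)
  expect_equal(fits$linear$dof, 32L)         # n - 2
  expect_equal(fits$linear_origin$dof, 33L)  # n - 1
  expect_equal(fits$quadratic$dof, 32L)      # n - 2
  expect_equal(fits$segmented$dof, 30L)      # n - 4, breakpoint estimated
})

test_that("breakpoint estimation finds a constructed kink and warns on linear data", {
  x <- seq(5, 50, length.out = 46)
  y <- ifelse(x <= 25, 1.2 * x, 1.2 * 25 + 0.6 * (x - 25))
  seg <- estimate_breakpoint(y, x)
  expect_equal(seg$breakpoint, 25, tolerance = 0.1)
  expect_equal(unname(seg$coefficients["slope1"]), 1.2, tolerance = 1e-6)
  expect_equal(unname(seg$coefficients["slope2"]), -0.6, tolerance = 1e-6)

  y_lin <- 2 + 0.9 * x
  expect_warning(estimate_breakpoint(y_lin, x), "boundary-breakpoint")

  # on quadratic-generated data the segmented form cannot beat the quadratic
  yq <- 1.006348 * x - 0.003437 * x^2
  fits <- suppressWarnings(fit_candidates(yq, x))
  expect_gte(fits$segmented$rse, fits$quadratic$rse - 1e-10)
})

test_that("model selection prefers the quadratic at the published AIC set", {
  cands <- list(
    correction_model("linear", c(intercept = 0, slope = 1), aic = 138.49),
    correction_model("linear_origin", c(slope = 1), aic = 147.49),
    correction_model("quadratic", c(a = 1.006348, b = 0.003437), aic = 135.23),
    correction_model("segmented", c(intercept = 0, slope1 = 1, slope2 = 0),
                     aic = 138.82, breakpoint = 23.7))
  expect_equal(select_correction(cands)$form, "quadratic")
  expect_equal(select_correction(cands[3])$form, "quadratic")  # single candidate
})

test_that("near-ties break toward the more interpretable form", {
  seg <- correction_model("segmented", c(intercept = 0, slope1 = 1, slope2 = 0),
                          aic = 100, breakpoint = 20)
  qd <- correction_model("quadratic", c(a = 1, b = 0.001), aic = 101)
  lin <- correction_model("linear", c(intercept = 0, slope = 1), aic = 101.5)
  expect_equal(select_correction(list(seg, qd, lin))$form, "quadratic")
  # a decisive AIC gap is respected
  qd2 <- correction_model("quadratic", c(a = 1, b = 0.001), aic = 103)
  expect_equal(select_correction(list(seg, qd2))$form, "segmented")
})

test_that("coefficients are recovered from noisy quadratic data", {
  set.seed(77)
  x <- runif(200, 8, 57)
  y <- (1.006348 * x - 0.003437 * x^2) * (1 + rnorm(200, 0, 0.05))
  q <- fit_candidates(y, x)$quadratic
  expect_lt(abs(unname(q$coefficients["a"]) - 1.006348), 0.05)
  expect_lt(abs(unname(q$coefficients["b"]) - 0.003437), 0.001)
})

test_that("fit diagnostics are invariant to reindexing of the pairs", {
  set.seed(9)
  x <- runif(30, 8, 55)
  y <- (1.006348 * x - 0.003437 * x^2) * (1 + rnorm(30, 0, 0.05))
  f1 <- suppressWarnings(fit_candidates(y, x))
  idx <- sample.int(30)
  f2 <- suppressWarnings(fit_candidates(y[idx], x[idx]))
  for (nm in names(f1)) {
    expect_equal(f1[[nm]]$aic, f2[[nm]]$aic, tolerance = 1e-9)
    expect_equal(f1[[nm]]$coefficients, f2[[nm]]$coefficients, tolerance = 1e-9)
  }
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_candidates(c(1, 2, 3), c(1, 2, 3, 4)), "lengths differ")
  expect_error(fit_candidates(1:5, 1:5), "insufficient-data")
  expect_error(fit_candidates(rep(2, 10), rep(3, 10)), "rank error")
  expect_error(fit_candidates(c(-1, 2:10), 1:10), "positive")
  expect_error(correction_coefficients(
    correction_model("linear", c(intercept = 0, slope = 1))), "quadratic")
})
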