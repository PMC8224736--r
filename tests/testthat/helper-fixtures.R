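# Shared fixtures, all generated in code.

# Profile lying exactly on C(t) = C1 * exp(-b1 * t) at the given times.
exact_mono_profile <- function(C1 = 100, b1 = 0.004,
                               times = c(180, 240, 300),
                               dose = 1500, species = "goat", wgt = 70) {
  concentration_profile("mono", 1L, species, wgt, dose,
                        times, C1 * exp(-b1 * times))
}

# Reference 3-compartment parameter set used across PK tests.
ref_params3 <- function(CL = 0.02) {
  micro_params(CL = CL, V1 = 6, Q2 = 0.1, V2 = 4, Q3 = 0.02, V3 = 6)
}

# Variance-free population: every draw reproduces the typical animal.
noiseless_spec <- function(...) {
  population_spec(iiv_sd = c(V2 = 0), iov_sd_cl = 0, error_sd = 0, ...)
}

# Random positive micro-parameters for property loops.
random_params <- function(n_compartments) {
  vals <- list(CL = stats::runif(1, 0.005, 0.06),
               V1 = stats::runif(1, 2, 10))
  if (n_compartments >= 2) {
    vals$Q2 <- stats::runif(1, 0.05, 0.5)
    vals$V2 <- stats::runif(1, 1, 8)
  }
  if (n_compartments == 3) {
    vals$Q3 <- stats::runif(1, 0.01, 0.12)
    vals$V3 <- stats::runif(1, 1, 10)
  }
  do.call(micro_params, vals)
}

# Concentrations by numerical integration of the mammillary ODE system;
# independent oracle for the closed-form solution.
ode_concentrations <- function(params, dose, times) {
  n <- params$n_compartments
  K <- if (n == 1L) matrix(-params$CL / params$V1, 1, 1) else
    iohexolGFR:::rate_matrix(params)
  out <- deSolve::ode(y = c(dose, rep(0, n - 1)),
                      times = sort(unique(c(0, times))),
                      func = function(t, y, p) list(K %*% y),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  out[match(times, out[, 1]), 2] / params$V1
}

default_schedule <- function() {
  c(5, 10, 20, 30, 60, 120, 180, 240, 300, 360, 480, 1440)
}
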