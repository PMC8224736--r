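# Closed-form linear mammillary disposition models for an IV bolus:
# micro-parameters -> sum-of-exponentials macro form -> predicted
# concentrations -> simulated occasions with proportional residual error.

#' Compartmental micro-parameters
#'
#' Container for the micro-parameterization of a 1-, 2- or 3-compartment
#' mammillary disposition model with linear elimination from the central
#' compartment. All quantities use internal units: clearances in L/min,
#' volumes in L. The compartment count is inferred from which peripheral
#' parameters are supplied.
#'
#' @param CL elimination clearance (L/min).
#' @param V1 central volume of distribution (L).
#' @param Q2,V2 intercompartmental clearance (L/min) and volume (L) of the
#'   first peripheral compartment; both or neither must be given.
#' @param Q3,V3 intercompartmental clearance and volume of the second
#'   peripheral compartment; require `Q2`/`V2`.
#' @return An object of class `micro_params` with fields `n_compartments`,
#'   `CL`, `V1` and, when present, `Q2`, `V2`, `Q3`, `V3`.
#' @examples
#' micro_params(CL = 0.02, V1 = 10)
#' micro_params(CL = 0.02, V1 = 6, Q2 = 0.1, V2 = 4, Q3 = 0.02, V3 = 6)
#' @export
micro_params <- function(CL, V1, Q2 = NULL, V2 = NULL, Q3 = NULL, V3 = NULL) {
  if (is.null(Q2) != is.null(V2)) stopf("Q2 and V2 must be supplied together")
  if (is.null(Q3) != is.null(V3)) stopf("Q3 and V3 must be supplied together")
  if (!is.null(Q3) && is.null(Q2)) {
    stopf("a third compartment (Q3/V3) requires a second (Q2/V2)")
  }
  n <- 1L + (!is.null(Q2)) + (!is.null(Q3))
  vals <- c(CL = CL, V1 = V1, Q2 = Q2, V2 = V2, Q3 = Q3, V3 = V3)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stopf("invalid parameter: all compartmental parameters must be finite and strictly positive")
  }
  structure(
    c(list(n_compartments = n), as.list(vals)),
    class = "micro_params"
  )
}

#' @export
print.micro_params <- function(x, ...) {
  cat(sprintf("%d-compartment micro-parameters (L, L/min):\n", x$n_compartments))
  v <- unlist(x[names(x) != "n_compartments"])
  print(signif(v, 6))
  invisible(x)
}

# Rate matrix of the mammillary amount system dA/dt = K A, bolus into
# compartment 1. Concentration observed as A1/V1.
rate_matrix <- function(p) {
  k10 <- p$CL / p$V1
  if (p$n_compartments == 2L) {
    k12 <- p$Q2 / p$V1; k21 <- p$Q2 / p$V2
    matrix(c(-(k10 + k12), k21,
             k12,          -k21), 2L, 2L, byrow = TRUE)
  } else {
    k12 <- p$Q2 / p$V1; k21 <- p$Q2 / p$V2
    k13 <- p$Q3 / p$V1; k31 <- p$Q3 / p$V3
    matrix(c(-(k10 + k12 + k13), k21,  k31,
             k12,                -k21, 0,
             k13,                0,    -k31), 3L, 3L, byrow = TRUE)
  }
}

#' Macro (sum-of-exponentials) coefficients of a disposition model
#'
#' Converts micro-parameters to the dose-normalized poly-exponential
#' solution \eqn{C(t) = \mathrm{dose} \sum_i A_i e^{-\lambda_i t}} of the
#' mammillary system with bolus input into the central compartment, by
#' eigendecomposition of the rate matrix. Amplitudes are per mg of dose
#' (units 1/L); rates are 1/min, returned in decreasing order.
#'
#' The representation satisfies the AUC identity
#' \eqn{\sum_i A_i/\lambda_i = 1/CL}, which is how total plasma clearance is
#' conserved by the transformation.
#'
#' @param params a [micro_params()] object.
#' @return An object of class `macro_coefficients` with fields `amplitudes`,
#'   `rates`, `n_compartments` and `CL`.
#' @examples
#' m <- micro_to_macro(micro_params(CL = 0.02, V1 = 10))
#' m$rates      # CL/V1 = 0.002 /min
#' m$amplitudes # 1/V1  = 0.1 per L
#' @export
micro_to_macro <- function(params) {
  if (!inherits(params, "micro_params")) {
    params <- do.call(micro_params, as.list(params[names(params) != "n_compartments"]))
  }
  n <- params$n_compartments
  if (n == 1L) {
    lambda <- params$CL / params$V1
    amp <- 1 / params$V1
  } else {
    K <- rate_matrix(params)
    eg <- eigen(K)
    lambda <- -Re(eg$values)
    gaps <- abs(diff(sort(lambda))) / max(lambda)
    if (any(gaps < 1e-12)) {
      stopf("degenerate-system: disposition eigenvalues coincide (relative gap < 1e-12)")
    }
    # initial amounts (1, 0, ...) per mg of dose; project onto eigenbasis
    coefs <- solve(eg$vectors, c(1, rep(0, n - 1L)))
    amp <- Re(eg$vectors[1L, ] * coefs) / params$V1
  }
  ord <- order(lambda, decreasing = TRUE)
  structure(
    list(amplitudes = amp[ord], rates = lambda[ord],
         n_compartments = n, CL = params$CL),
    class = "macro_coefficients"
  )
}

#' @export
print.macro_coefficients <- function(x, ...) {
  cat(sprintf("%d-exponential disposition: C(t) = dose * sum A_i exp(-lambda_i t)\n",
              x$n_compartments))
  print(data.frame(amplitude_per_L = signif(x$amplitudes, 6),
                   rate_per_min = signif(x$rates, 6)))
  invisible(x)
}

#' Predict plasma concentrations after an IV bolus
#'
#' Evaluates the poly-exponential disposition curve at the requested times.
#'
#' @param macro a [micro_to_macro()] result (or a `micro_params` object,
#'   converted on the fly).
#' @param dose bolus amount (mg), administered at time 0.
#' @param times sampling times (min), all non-negative.
#' @return Numeric vector of concentrations (mg/L).
#' @examples
#' m <- micro_to_macro(micro_params(CL = 0.02, V1 = 10))
#' predict_concentration(m, dose = 1500, times = c(0, 300))
#' @export
predict_concentration <- function(macro, dose, times) {
  if (inherits(macro, "micro_params")) macro <- micro_to_macro(macro)
  dose <- check_dose(dose)
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0)) {
    stopf("times must be finite and non-negative (min)")
  }
  drop(exp(outer(times, -macro$rates)) %*% macro$amplitudes) * dose
}

#' A single sampling occasion's concentration-time profile
#'
#' One animal-occasion: species, body weight, dose and an ordered series of
#' (time, concentration) samples with per-sample QC flags. This is the unit
#' of data every estimator in the package consumes.
#'
#' @param subject_id subject label.
#' @param occasion occasion index (integer >= 1).
#' @param species `"goat"` or `"pig"`.
#' @param bodyweight body weight (kg).
#' @param dose IV bolus amount (mg) at time 0.
#' @param times sampling times (min, strictly increasing, > 0 post-dose;
#'   a time-0 pre-dose row is permitted and flagged `"excluded"`).
#' @param concentrations iohexol plasma concentrations (mg/L, >= 0).
#' @param flags per-sample flags in `ok`, `blq`, `outlier`, `excluded`;
#'   recycled from a single value.
#' @param lloq lower limit of quantification of the assay (mg/L).
#' @param state health state label, `"healthy"` or `"ckd"` (optional
#'   metadata used by the simulator and reports).
#' @return An object of class `concentration_profile`: a list with the
#'   scalar fields above and a `samples` data frame
#'   (`time`, `conc`, `flag`).
#' @export
concentration_profile <- function(subject_id, occasion, species, bodyweight,
                                  dose, times, concentrations,
                                  flags = "ok", lloq = 1,
                                  state = NA_character_) {
  species <- match_species(species)
  dose <- check_dose(dose)
  if (!is.numeric(bodyweight) || bodyweight <= 0) stopf("bodyweight must be positive (kg)")
  if (length(times) != length(concentrations)) {
    stopf("times and concentrations must have equal length")
  }
  if (length(times) == 0L) stopf("profile must contain at least one sample")
  if (any(!is.finite(times)) || any(times < 0)) stopf("sample times must be non-negative")
  if (any(diff(times) <= 0)) stopf("sample times must be strictly increasing")
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stopf("concentrations must be non-negative")
  }
  if (lloq <= 0) stopf("lloq must be positive (mg/L)")
  flags <- rep_len(as.character(flags), length(times))
  bad <- setdiff(unique(flags), c("ok", "blq", "outlier", "excluded"))
  if (length(bad)) stopf("unknown sample flag(s): %s", paste(bad, collapse = ", "))
  flags[times == 0] <- "excluded"  # pre-dose baseline never enters a regression
  structure(
    list(subject_id = as.character(subject_id),
         occasion = as.integer(occasion),
         species = species,
         bodyweight = as.double(bodyweight),
         dose = dose,
         lloq = as.double(lloq),
         state = state,
         samples = data.frame(time = as.double(times),
                              conc = as.double(concentrations),
                              flag = flags,
                              stringsAsFactors = FALSE)),
    class = "concentration_profile"
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: %s occasion %d (%s, %.1f kg, %g mg IV bolus)\n",
              x$subject_id, x$occasion, x$species, x$bodyweight, x$dose))
  cat(sprintf("  %d samples, %d usable; LLOQ %g mg/L\n",
              nrow(x$samples), sum(x$samples$flag == "ok"), x$lloq))
  invisible(x)
}

# Samples usable for regression: flagged "ok" and strictly post-dose.
usable_samples <- function(profile) {
  s <- profile$samples
  s[s$flag == "ok" & s$time > 0, , drop = FALSE]
}

#' Simulate one sampling occasion
#'
#' Draws observed concentrations under a proportional residual-error model,
#' `obs = pred * (1 + eps)` with `eps ~ N(0, error_sd^2)`. Negative draws
#' (possible only at large `error_sd`) are truncated at zero and flagged
#' `"blq"`; the count of truncated draws is stored in the profile as
#' `n_truncated`.
#'
#' @param params a [micro_params()] object (the occasion's true parameters).
#' @param dose IV bolus amount (mg).
#' @param schedule sampling times (min, strictly increasing, non-empty).
#' @param error_sd proportional residual SD (fraction; 0 gives noiseless
#'   predictions).
#' @param seed optional integer; fixes the draw without disturbing the
#'   caller's RNG stream.
#' @param subject_id,occasion,species,bodyweight,lloq,state profile metadata,
#'   see [concentration_profile()].
#' @return A [concentration_profile()].
#' @export
simulate_occasion <- function(params, dose, schedule, error_sd,
                              seed = NULL,
                              subject_id = "sim", occasion = 1L,
                              species = "goat", bodyweight = 70,
                              lloq = 1, state = NA_character_) {
  if (length(schedule) == 0L) stopf("schedule must contain at least one time")
  if (!is.numeric(error_sd) || error_sd < 0) stopf("error_sd must be >= 0")
  pred <- predict_concentration(micro_to_macro(params), dose, schedule)
  obs <- with_seed(seed, pred * (1 + stats::rnorm(length(pred), 0, error_sd)))
  truncated <- obs < 0
  obs[truncated] <- 0
  flags <- ifelse(truncated, "blq", "ok")
  out <- concentration_profile(subject_id, occasion, species, bodyweight,
                               dose, schedule, obs, flags, lloq, state)
  out$true_params <- params
  out$n_truncated <- sum(truncated)
  out
}

#' Flag samples below the lower limit of quantification
#'
#' Samples with concentration strictly below the profile's LLOQ are flagged
#' `"blq"` and thereby excluded from every downstream regression. The count
#' of newly plus previously flagged BLQ samples is stored as `n_blq`.
#'
#' @param profile a [concentration_profile()].
#' @return The profile with updated flags and an `n_blq` field.
#' @export
apply_lloq <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  s <- profile$samples
  below <- s$conc < profile$lloq & s$flag == "ok"
  s$flag[below] <- "blq"
  profile$samples <- s
  profile$n_blq <- sum(s$flag == "blq")
  profile
}
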