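# Calibration of the correction relationship between the slope-intercept
# clearance (x = CL_1CMT) and the reference clearance (y = CL_ref):
# four candidate forms, diagnostics, breakpoint estimation, and selection.

#' Construct a correction model
#'
#' Builds a `correction_model` object directly; mainly for programmatic
#' use (e.g. comparing externally reported candidates). [fit_candidates()]
#' is the usual constructor.
#'
#' @param form one of `"linear"`, `"linear_origin"`, `"quadratic"`,
#'   `"segmented"`.
#' @param coefficients named numeric vector. Expected names:
#'   `intercept`/`slope` (linear), `slope` (linear_origin), `a`/`b`
#'   (quadratic, for `y = a x - b x^2`), `intercept`/`slope1`/`slope2`
#'   (segmented, `slope2` the second-segment slope).
#' @param rse residual standard error (mL/min).
#' @param aic Akaike information criterion.
#' @param adj_r2 adjusted R-squared.
#' @param dof residual degrees of freedom (n minus number of estimated
#'   parameters, the breakpoint counting as one).
#' @param coef_se named standard errors of the coefficients.
#' @param breakpoint breakpoint (mL/min); segmented form only.
#' @return An object of class `correction_model`.
#' @export
correction_model <- function(form, coefficients, rse = NA_real_,
                             aic = NA_real_, adj_r2 = NA_real_,
                             dof = NA_integer_, coef_se = NULL,
                             breakpoint = NA_real_) {
  form <- match.arg(form, c("linear", "linear_origin", "quadratic", "segmented"))
  structure(list(form = form, coefficients = coefficients, rse = rse,
                 aic = aic, adj_r2 = adj_r2, dof = dof, coef_se = coef_se,
                 breakpoint = breakpoint),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  eqn <- switch(x$form,
    linear = sprintf("y = %.4g + %.4g x", x$coefficients["intercept"],
                     x$coefficients["slope"]),
    linear_origin = sprintf("y = %.4g x", x$coefficients["slope"]),
    quadratic = sprintf("y = %.6f x - %.6f x^2", x$coefficients["a"],
                        x$coefficients["b"]),
    segmented = sprintf("y = %.4g + %.4g x + %.4g (x - %.4g)+",
                        x$coefficients["intercept"], x$coefficients["slope1"],
                        x$coefficients["slope2"], x$breakpoint))
  cat(sprintf("Correction model [%s]: %s\n", x$form, eqn))
  cat(sprintf("  RSE %.4g on %d DF, adj R2 %.4f, AIC %.2f\n",
              x$rse, x$dof, x$adj_r2, x$aic))
  invisible(x)
}

#' Predict corrected clearance from a correction model
#'
#' @param object a `correction_model`.
#' @param cl_1cmt one-compartment clearances (mL/min).
#' @param ... unused.
#' @return Predicted reference-scale clearances (mL/min).
#' @export
predict.correction_model <- function(object, cl_1cmt, ...) {
  co <- object$coefficients
  switch(object$form,
         linear = unname(co["intercept"] + co["slope"] * cl_1cmt),
         linear_origin = unname(co["slope"] * cl_1cmt),
         quadratic = unname(co["a"] * cl_1cmt - co["b"] * cl_1cmt^2),
         segmented = unname(co["intercept"] + co["slope1"] * cl_1cmt +
                              co["slope2"] * pmax(cl_1cmt - object$breakpoint, 0)))
}

check_pairs <- function(cl_ref, cl_1cmt, n_min = 6L) {
  if (length(cl_ref) != length(cl_1cmt)) stopf("cl_ref and cl_1cmt lengths differ")
  ok <- is.finite(cl_ref) & is.finite(cl_1cmt)
  if (any(cl_ref[ok] <= 0) || any(cl_1cmt[ok] <= 0)) {
    stopf("clearance pairs must be strictly positive")
  }
  if (sum(ok) < n_min) {
    stopf("insufficient-data: %d usable pairs, need >= %d", sum(ok), n_min)
  }
  if (stats::sd(cl_1cmt[ok]) < 1e-12) stopf("rank error: cl_1cmt is constant")
  data.frame(x = cl_1cmt[ok], y = cl_ref[ok])
}

from_lm <- function(fit, form, coef_names, k_extra = 0L) {
  sm <- suppressWarnings(summary(fit))  # exact recovery is a legitimate input
  co <- stats::coef(fit)
  names(co) <- coef_names
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- coef_names
  correction_model(
    form = form, coefficients = co,
    rse = sm$sigma, aic = stats::AIC(fit),
    adj_r2 = sm$adj.r.squared,
    dof = stats::df.residual(fit) - k_extra,
    coef_se = se
  )
}

#' Fit the four candidate correction relationships
#'
#' Regresses reference clearance `y` on one-compartment clearance `x`
#' under the four candidate forms: (i) linear `y = c0 + c1 x`;
#' (ii) linear through the origin `y = c1 x`; (iii) quadratic with no
#' intercept `y = a x - b x^2` (least squares on the design `{x, -x^2}`);
#' (iv) continuous two-segment linear with an estimated breakpoint
#' ([estimate_breakpoint()]). Each fit reports RSE, AIC, adjusted
#' R-squared, residual DF and coefficient SEs.
#'
#' @param cl_ref reference clearances (mL/min).
#' @param cl_1cmt paired one-compartment clearances (mL/min); n >= 6.
#' @param grid_resolution breakpoint grid step (mL/min) for the segmented
#'   candidate.
#' @return Named list of four [correction_model()]s:
#'   `linear`, `linear_origin`, `quadratic`, `segmented`.
#' @export
fit_candidates <- function(cl_ref, cl_1cmt, grid_resolution = 0.1) {
  d <- check_pairs(cl_ref, cl_1cmt)
  lin <- stats::lm(y ~ x, data = d)
  org <- stats::lm(y ~ x - 1, data = d)
  qd <- stats::lm(y ~ 0 + x + I(-x^2), data = d)
  seg <- suppressWarnings(
    estimate_breakpoint(d$y, d$x, grid_resolution = grid_resolution))
  list(
    linear = from_lm(lin, "linear", c("intercept", "slope")),
    linear_origin = from_lm(org, "linear_origin", "slope"),
    quadratic = from_lm(qd, "quadratic", c("a", "b")),
    segmented = seg
  )
}

#' Estimate the breakpoint of a two-segment linear correction
#'
#' Profiles the residual sum of squares of the continuous two-segment
#' model `y = c0 + c1 x + c2 (x - psi)+` over a breakpoint grid spanning
#' the central 80% of observed `x` (10th to 90th percentile) at the given
#' resolution, then refines the RSS-minimizing grid point by local
#' univariate search. A minimum on the grid boundary (as happens for
#' exactly linear data) raises a boundary-breakpoint warning.
#'
#' @inheritParams fit_candidates
#' @return A `correction_model` of form `"segmented"`. The breakpoint
#'   counts as an estimated parameter in `dof` and `aic`.
#' @export
estimate_breakpoint <- function(cl_ref, cl_1cmt, grid_resolution = 0.1) {
  d <- check_pairs(cl_ref, cl_1cmt)
  lo <- stats::quantile(d$x, 0.1, names = FALSE)
  hi <- stats::quantile(d$x, 0.9, names = FALSE)
  if (hi - lo < 2 * grid_resolution) stopf("rank error: x range too narrow for a breakpoint grid")
  grid <- seq(lo, hi, by = grid_resolution)
  rss_at <- function(psi) {
    sum(stats::resid(stats::lm(y ~ x + pmax(x - psi, 0), data = d))^2)
  }
  rss <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rss)
  if (i == 1L || i == length(grid)) {
    warnf("boundary-breakpoint: RSS profile has no interior minimum (breakpoint at %g)",
          grid[i])
    psi <- grid[i]
  } else {
    psi <- stats::optimize(rss_at, c(grid[i - 1L], grid[i + 1L]))$minimum
  }
  fit <- stats::lm(y ~ x + pmax(x - psi, 0), data = d)
  n <- nrow(d)
  k <- 4L  # intercept, two slopes, breakpoint
  rss_min <- sum(stats::resid(fit)^2)
  tss <- sum((d$y - mean(d$y))^2)
  co <- stats::coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  names(co) <- names(se) <- c("intercept", "slope1", "slope2")
  correction_model(
    form = "segmented", coefficients = co,
    rse = sqrt(rss_min / (n - k)),
    # same likelihood form as stats::AIC on a Gaussian lm, with k + sigma
    aic = n * log(2 * pi * rss_min / n) + n + 2 * (k + 1),
    adj_r2 = 1 - (rss_min / (n - k)) / (tss / (n - 1)),
    dof = n - k, coef_se = se, breakpoint = psi
  )
}

#' Select the correction model
#'
#' Minimum-AIC selection with an interpretability tie-break: all candidates
#' within 2 AIC units of the minimum are considered equivalent and the
#' first in the fixed preference order quadratic, linear, linear-origin,
#' segmented wins. (A segmented model that does not clearly outperform the
#' quadratic is harder to interpret and apply, hence ranked last.)
#'
#' @param candidates list of [correction_model()]s (>= 1), e.g. from
#'   [fit_candidates()].
#' @return The selected `correction_model`.
#' @examples
#' cands <- list(
#'   correction_model("linear", c(intercept = 0, slope = 1), aic = 138.49),
#'   correction_model("linear_origin", c(slope = 1), aic = 147.49),
#'   correction_model("quadratic", c(a = 1.006348, b = 0.003437), aic = 135.23),
#'   correction_model("segmented", c(intercept = 0, slope1 = 1, slope2 = 0),
#'                    aic = 138.82, breakpoint = 23.7))
#' select_correction(cands)$form  # "quadratic"
#' @export
select_correction <- function(candidates) {
  if (inherits(candidates, "correction_model")) return(candidates)
  stopifnot(length(candidates) >= 1)
  if (length(candidates) == 1L) return(candidates[[1L]])
  aics <- vapply(candidates, `[[`, numeric(1), "aic")
  forms <- vapply(candidates, `[[`, character(1), "form")
  best <- min(aics, na.rm = TRUE)
  eligible <- which(is.finite(aics) & aics - best < 2)
  preference <- c("quadratic", "linear", "linear_origin", "segmented")
  ranks <- match(forms[eligible], preference)
  candidates[[eligible[which.min(ranks)]]]
}

#' Correction coefficients usable by [cl_simplified()]
#'
#' @param model a quadratic `correction_model`.
#' @return Numeric `c(a, b)`.
#' @export
correction_coefficients <- function(model) {
  stopifnot(inherits(model, "correction_model"))
  if (model$form != "quadratic") {
    stopf("coefficients in cl_simplified() form require a quadratic model; got '%s'",
          model$form)
  }
  c(a = unname(model$coefficients["a"]), b = unname(model$coefficients["b"]))
}
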