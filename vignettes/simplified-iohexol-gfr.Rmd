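---
title: "Measuring GFR in goats and pigs from three iohexol samples: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring GFR in goats and pigs from three iohexol samples: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Preclinical work on kidney therapies needs repeated measurement of
glomerular filtration rate (GFR) in large uremic animals. The reference
techniques — continuous inulin infusion with timed urine collection, or
rich-sampling plasma clearance with population pharmacokinetic (PK)
modelling — are slow, invasive, and need specialist software. The
simplified method implemented here needs a single 1500-mg IV bolus of
iohexol and three venous samples at 180, 240 and 300 min.

Iohexol is eliminated essentially only by glomerular filtration, so its
plasma clearance (dose over the area under the concentration–time curve,
`CL = dose / AUC`) measures GFR. After a bolus its profile is
tri-exponential: two distribution phases followed by a mono-exponential
terminal phase. Fitting only the terminal phase treats the animal as a
one-compartment system and therefore *underestimates the AUC* (it misses
the area under the distribution phases), so the resulting slope–intercept
clearance overestimates true clearance — by more at high clearance, where
the distribution area is a larger fraction of the total. A
Bröchner–Mortensen-type polynomial correction repairs exactly this.

## The simplified method

For one occasion, with dose $Q_{inf}$ (mg) and concentrations $C$ (mg/L)
at $t$ = 180, 240, 300 min:

1. **Terminal fit** (`fit_terminal_slope`): ordinary least squares of
   $\log C$ on $t$, giving back-transformed intercept $C_1$ (mg/L) and
   terminal rate $b_1 = -\text{slope}$ (1/min). Natural logs are used;
   the base cancels out of the clearance.
2. **Slope–intercept clearance** (`cl_one_compartment`):
   $CL_{1CMT} = Q_{inf}\, b_1 / C_1$, i.e. dose over the one-compartment
   AUC $C_1/b_1$; reported in mL/min.
3. **Quadratic correction** (`cl_simplified`):
   $CL_{SM} = a\,CL_{1CMT} - b\,CL_{1CMT}^2$ with shipped coefficients
   $a = 1.006348$, $b = 0.003437$ (mL/min)$^{-1}$, calibrated in goats and
   pigs over clearances up to 57.28 mL/min. Past the vertex
   $a/2b \approx 146$ mL/min the parabola turns over, so inputs above the
   calibration range trigger a warning rather than silent extrapolation.
4. **BSA normalization** (`body_surface_area`, `normalize_gfr`): Saito's
   goat formula $W^{0.62}\cdot 1147.7/10^4$ and Kelly's pig formula
   $W^{0.656}\cdot 734/10^4$ (m²), then
   $mGFR = CL / BSA \times \text{const}$ with the standardized 70-kg
   constants 1.43 m² (goat) and 1.19 m² (pig). Note an internal quirk of
   the published formulas, reproduced deliberately: Saito's equation at
   70 kg gives 1.599 m², not 1.43; the per-animal BSA uses the formula,
   the standardization uses the printed constant. For a 70-kg pig the
   two cancel exactly.

Why the quadratic has this form: write $m$ for the dose-normalized
distribution-phase AUC that the terminal fit cannot see
($m = A_1/\lambda_1 + A_2/\lambda_2$ in the tri-exponential
parameterization, min/L). Then $CL_{1CMT} = CL/(1 - m\,CL)$ exactly for
noiseless kinetics, and inverting gives
$CL = x/(1 + m x) \approx x - m x^2$ for $x = CL_{1CMT}$. The fitted $b$
is therefore a physiological quantity — the missing distribution area —
and the shipped $b = 0.003437$ (mL/min)$^{-1}$ corresponds to
$m \approx 3.4$ min/L.

## Quality control

Mirroring the exclusions used when the correction was derived
(`qc_screen`):

* samples below the assay LLOQ (default 1 mg/L, configurable) are
  flagged `blq` and never enter a regression;
* samples above `max_concentration` (default: the dose in mg, i.e. the
  concentration the whole bolus would give dissolved in one litre) are
  flagged `outlier` — this generalizes a single observed 11,317 mg/L
  artifact without inventing a distributional test;
* an observed maximum later than `tmax_limit` (default 10 min, the first
  two scheduled samples) is physiologically impossible after an IV bolus
  and marks the occasion as extravasated, excluding it;
* fewer than two usable terminal samples, or a non-negative terminal
  slope, exclude the occasion with a logged reason.

## The reference method at desk scale

The correction is calibrated against a reference clearance from rich
sampling (12 post-dose samples over 24 h). The original derivation used
population NLME estimation; this package deliberately does not
re-implement a NONMEM-style FOCE-I estimator. Only *individual* clearances
feed the calibration, so `fit_occasion` uses the classical two-stage
analogue: per-occasion weighted nonlinear least squares on 1-, 2- and
3-compartment bolus models, with

* proportional weighting (residuals $(obs - pred)/pred$), matching the
  proportional residual-error model;
* log-parameterization for positivity, Levenberg–Marquardt iterations
  (`minpack.lm`), convergence at $10^{-10}$ relative objective change,
  at most 2000 evaluations per start;
* five multi-starts: curve-stripping initial values (terminal slope for
  $\lambda_z$, trapezoid-plus-tail AUC for CL, first-sample
  back-extrapolation for $V_1$) plus seeded log-uniform jitter of ±0.7;
* compartment-number selection by per-occasion AIC
  ($n\log(RSS/n) + 2(k+1)$), with a nested pseudo-likelihood-ratio rule
  (3.84 per two parameters) available as `criterion = "lrt"`.

**Identifiability guard.** Sum-of-exponentials fits admit degenerate
solutions that match the data arbitrarily well while leaving the AUC —
and hence CL — completely unidentified: an exponential spike confined to
a single early sample, or a near-zero rate acting as a constant offset
whose AUC lies entirely beyond the last sample. `fit_occasion` rejects a
solution as rank-deficient when any mode contributes more than 1% of the
predicted concentration at fewer than two observed times, or when the
fitted model places more than 80% of its AUC after the last sample.
Multi-start prefers identifiable solutions; if none exists the result is
flagged `converged = FALSE` and selection falls back to the best
converged candidate (typically the 2-compartment model, whose clearance
is nearly unbiased for this design).

## Calibration of the correction

`fit_candidates` regresses reference clearance $y$ on slope–intercept
clearance $x$ under four forms: linear, linear through the origin,
quadratic without intercept ($y = a x - b x^2$, least squares on the
design $\{x, -x^2\}$), and a continuous two-segment linear model. The
segmented breakpoint is estimated by profiling the residual sum of
squares over a grid spanning the 10th–90th percentile of $x$ at
0.1 mL/min resolution, refined by local univariate search — numerically
equivalent, at that resolution, to iterative segmented-regression
packages, and transparent about flat profiles (a boundary minimum raises
a warning instead of reporting a spurious interior break).

`select_correction` takes the minimum-AIC candidate, except that
candidates within 2 AIC units are treated as equivalent and the fixed
preference order quadratic > linear > linear-origin > segmented applies:
a segmented model that does not clearly outperform the quadratic is
harder to interpret and apply in the field. The breakpoint counts as an
estimated parameter in the segmented model's AIC and degrees of freedom.

A single pooled correction is fitted across species (no species-dependent
bias was evident in the original comparison); per-species calibration is
available by simply subsetting the pairs.

## Agreement statistics

`bland_altman` orients differences as reference minus estimate, reports
bias, SD of differences, limits of agreement at ±1.96 SD, t-based 95% CI
for the bias and the $SD\sqrt{3/n}$ approximation for the limits.
The *precision of agreement* divides 2·SD of the differences by the grand
mean of the per-pair means — this denominator is a convention choice,
stated here because it is easy to conflate with `precision_metric`
(2·SD/mean of one method's values), which measures the spread of
clearances across occasions, not method disagreement. `p_within` uses an
inclusive boundary ($|est-ref|/ref \le$ tolerance). Sample SDs use the
$n-1$ denominator throughout. Repeated occasions within one animal are
pooled, not modelled hierarchically.

## The synthetic cohort generator

No animal data are distributed, so `simulate_cohort` generates the study
design: goats of 48–84 kg and pigs of 34–80 kg, each measured in a
healthy state and again after induction of chronic kidney disease, 12
post-dose samples at 5–1440 min, 1500 mg dose. Individual parameters are
typical values scaled allometrically (exponent 0.75 for clearances, 1.0
for volumes, reference 70 kg), multiplied by a pig/goat clearance factor
(default 1.10) and lognormal random effects: inter-individual SD 0.3 on
the peripheral volume, inter-occasion SD 0.15 on clearance. CKD
multiplies clearance by a per-animal uniform(0.25, 0.6) fraction,
emulating embolization of roughly 80% of one kidney and all of the
other. Observations get proportional Gaussian error; negative draws are
truncated at zero and flagged.

The typical disposition parameters (70-kg goat: CL 0.036 L/min, V1 2.2 L,
Q2 0.30 L/min, V2 1.25 L, Q3 0.055 L/min, V3 2.3 L) are **package
choices, not estimates from any animal dataset** — the original
population estimates are not available. They were calibrated once
against the published study-level anchors and then frozen:

* true clearances across healthy and CKD occasions span roughly
  7–47 mL/min;
* the noiseless slope–intercept clearance maps back through the shipped
  quadratic to within about 2% over that whole range (i.e. the
  generator's missing distribution area $m \approx 3.2$–3.6 min/L matches
  the shipped $b$), and 47 mL/min of true clearance yields a
  slope–intercept value near the top of the published calibration range;
* terminal half-life is about 2 h in healthy animals and several-fold
  longer with CKD, and the 1440-min sample of healthy animals falls
  below the 1 mg/L LLOQ, reproducing the ~3% BLQ bookkeeping of the
  original dataset.

**Residual error default (3%) and kinetic volumes.** The SE of the
terminal log-slope from three samples is $\sigma/\sqrt{S_{xx}} =
\sigma/84.85$ per min regardless of the animal, so the relative
uncertainty of $b_1$ — and with it the dispersion of the whole
method-comparison — is set by $\sigma$ and by how steep the terminal
slope is. Working backwards from the published agreement dispersion
(reference/simplified ratio 1.00 ± 0.07, quadratic residual SE
1.67 mL/min) at the study's clearance range forces an assay-scale
$\sigma$ of about 3% together with terminal volumes of distribution
around 5–7 L; a 10% residual error, or extracellular-water-sized volumes
(~14 L at 70 kg), would make the three-sample method's low-clearance
estimates several-fold noisier than anything the published statistics
could have come from. The generator therefore defaults to
`error_sd = 0.03` with the compact volumes above. Both are configurable,
and the reference-fit validation properties are exercised at 10% error,
where the rich 12-point design is unaffected.

What the generator does *not* emulate: assay batch effects or correlated
residuals, disease progression over calendar time, correlation between
random effects, extravasation events and gross sampling artifacts (QC
tests construct those explicitly), and any real between-species kinetic
differences beyond a clearance scale factor. Passing the simulation
loops therefore shows internal consistency of estimator, correction and
statistics under the stated model — not field performance on real
animals.

## Reproducibility and problem sizes

Every stochastic function takes a seed; cohort simulation derives
per-animal and per-occasion substreams from one root seed, so results do
not depend on iteration order, and the caller's RNG state is always
restored. The package's own validation runs use: 100 random parameter
sets per compartment count for the closed-form-vs-ODE oracle (tolerance
1e-8 relative); 500 simulated occasions at 10% noise for reference-fit
bias (within ±2%); 100 replicates for compartment-number selection
(3-compartment truth identified in at least 80%); and a 36-occasion
cohort for the calibration self-consistency loop, where the refitted
quadratic yields a mean reference/corrected ratio within [0.97, 1.03]
with SD below 0.15. The `scripts/acceptance.R` entry point re-runs that
last loop end to end from a user-supplied seed.

## Known limitations

* The reference estimator is a per-occasion two-stage fit, not population
  NLME: it does not borrow strength across occasions, and its RSEs are
  conditional on the selected model.
* The quadratic correction is only valid inside its calibration range;
  the implementation warns, but cannot repair, extrapolation.
* Agreement statistics treat repeated measurements in the same animal as
  independent; with few animals the confidence intervals are optimistic.
* BSA normalization inherits the published formulas' internal
  inconsistency for goats (1.599 m² formula value vs 1.43 m² printed
  constant at 70 kg); mGFR values are therefore comparable within this
  convention, not across conventions.
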