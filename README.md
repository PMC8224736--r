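# iohexolGFR

Measured glomerular filtration rate (mGFR) in goats and pigs from the
plasma clearance of iohexol, using only **three blood samples** after a
single 1500-mg IV bolus.

Preclinical evaluation of kidney therapies needs repeated GFR
measurement in large uremic animals, but the classical techniques
(continuous inulin infusion with urine collection, or rich-sampling
plasma clearance with population PK modelling) are invasive and slow.
This package implements the simplified alternative and everything needed
to derive, re-calibrate and validate it:

* **Simplified method** (`fit_terminal_slope`, `cl_one_compartment`,
  `cl_simplified`, `normalize_gfr`): log-linear regression of the
  180/240/300-min concentrations gives the terminal intercept C₁ (mg/L)
  and rate b₁ (1/min); the slope–intercept clearance
  `CL_1CMT = dose · b₁ / C₁` overestimates true clearance because it
  ignores the distribution phases, and the species-pooled quadratic
  correction

  `CL_SM = 1.006348 · CL_1CMT − 0.003437 · CL_1CMT²`   (mL/min)

  maps it onto the reference clearance. mGFR normalizes by body surface
  area (Saito for goats, Kelly for pigs) to a standardized 70-kg animal.
* **Forward PK models** (`micro_to_macro`, `predict_concentration`,
  `simulate_occasion`): exact sum-of-exponentials solutions of 1/2/3-
  compartment IV-bolus models via eigendecomposition, with proportional
  residual error and LLOQ censoring.
* **Synthetic cohorts** (`population_spec`, `simulate_cohort`): the
  study design — goats 48–84 kg, pigs 34–80 kg, healthy and CKD states
  per animal, lognormal IIV/IOV, allometric scaling.
* **Reference clearance** (`fit_occasion`, `select_compartments`,
  `reference_clearance`): per-occasion weighted nonlinear least squares
  with multi-start Levenberg–Marquardt, identifiability guards and
  AIC-based compartment selection.
* **Calibration** (`fit_candidates`, `estimate_breakpoint`,
  `select_correction`): the four candidate corrections (linear, linear
  through origin, quadratic, two-segment linear with estimated
  breakpoint) with RSE/AIC/adjusted-R² diagnostics.
* **Agreement statistics** (`bland_altman`, `precision_metric`,
  `p_within`, `ratio_stats`, `agreement_summary`): Bland–Altman bias
  and limits with 95% CIs, precision (2·SD/mean·100%), P30/P10.
* **Orchestration** (`run_pipeline`, `read_study_table`): long-format
  CSV I/O, YAML configuration, a full simulate → QC → estimate →
  calibrate → agree pipeline with an auditable exclusion log, and a CLI
  wrapper in `inst/scripts/iohexol-gfr.R`.

## Worked example

```r
library(iohexolGFR)

spec    <- population_spec()                       # study-like population
animal  <- draw_individual(spec, "goat", "ckd", seed = 42,
                           subject_id = "goat01")  # one uremic goat
profile <- animal$occasions[[1]]                   # 12-point rich profile

estimate_clearance(profile)   # the three-sample simplified method
#> Clearance estimate (goat01 occasion 1, goat):
#>   CL_1CMT 25.80 mL/min -> CL_SM 23.68 mL/min; mGFR_SM 19.35 mL/min/std BSA

sel <- select_compartments(qc_screen(profile)$profile, seed = 42)
reference_clearance(sel)      # rich-sampling reference for comparison
#> [1] 24.37
```

The simplified method uses only the 180/240/300-min samples of that
profile: the raw slope–intercept clearance (25.80 mL/min) overshoots,
the quadratic correction pulls it to 23.68 mL/min, within ~3% of the
rich-sampling reference (24.37 mL/min) — and the simulated animal's true
clearance was 24.51 mL/min. `normalize_gfr` scaled the corrected
clearance by this 80.9-kg goat's Saito BSA to the standardized 70-kg
value of 19.35 mL/min.

The full pipeline on a synthetic cohort, re-deriving the correction from
scratch:

```r
bundle <- run_pipeline(run_config(n_goats = 4, n_pigs = 5,
                                  occasions_per_state = 2, seed = 1))
bundle$correction       # selected correction with diagnostics
bundle$agreement_cl     # Bland-Altman, precision, P30/P10, ratio stats
```

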