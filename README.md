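# lipolyzer

Who controls the rate at which lipoprotein lipase (LPL) — the enzyme
that clears triglycerides from blood — hydrolyzes the triglyceride-rich
lipoproteins in a given person's plasma? Candidate answers are the
circulating regulator proteins (ANGPTL3/4/8, ApoC1/C2/C3, ApoA5) and the
physical properties of the lipoprotein particles themselves (sizes,
concentrations, compositions, fatty-acid saturation). `lipolyzer` is an R
package for cohort studies that address this question with an isothermal
titration calorimetry (ITC) activity assay as the outcome and an NMR
lipidomics panel plus regulator-protein immunoassays as predictors.

The package covers the pipeline end to end:

* **ITC extraction** — from a thermogram (differential power, uJ/s,
  versus time) with a purge + 3 x 5 uL injection schedule of 40 nM LPL
  into a 200 uL plasma cell, to an activity value: median baselines with
  injection-peak exclusion, the purge level as zero point, activity = the
  magnitude of the baseline shift across the first substantive injection,
  a linearity control against the cumulative enzyme concentration
  (volume-displacement dilution: each 5 uL injection adds ~1 nM), and
  bracketing-standards correction for inter-assay drift.
* **Preprocessing** — mass/molar unit conversions with protein molar
  masses, deterministic low-quantile imputation of left-censored panel
  cells, per-analysis listwise exclusion of missing-at-random values,
  z-standardization, and a cohort description table (mean/SD or
  median/IQR by skewness).
* **Association screening** — univariate OLS per predictor: effects in
  uJ/s per 1 SD (NMR variables) or per concentration unit (regulators),
  bootstrap distributions of the conditional R² (case resampling,
  B = 10,000), and the Spearman correlation matrix of the panel ordered
  by hierarchical clustering.
* **Multiplicity control** — fixed Bonferroni (0.05/9 ≈ 0.006) for the
  regulator family; for the collinear NMR panel, the effective number of
  independent tests m_eff = the number of principal components of the
  correlation matrix explaining 99.5% of the variance, giving
  0.05/m_eff thresholds and correspondingly widened confidence
  intervals (a 117-subject reference panel gives m_eff = 22, i.e.
  0.05/22 ≈ 0.002).
* **Synthetic cohorts with ground truth** — a 2-latent-factor generator
  (VLDL-size, HDL-size) reproducing the panel's block collinearity,
  log-normal regulator marginals parameterized by published
  medians/IQRs, a calibrated outcome (mean 0.72, SD 0.37 uJ/s), low-tail
  left-censoring (0.4% of cells in ≤ 6 subjects), and simulated
  thermograms — so every stage is testable without access to any cohort
  data.

For each predictor x, the fitted model is `y = alpha + beta x + eps` with
`y` the LPL activity; the screen reports beta, its classical SE and
t-test p-value, the in-sample R² (%), and a CI at level 1 − 0.05/m. See
the methods vignette (`vignettes/lpl-plasma-activity.Rmd`) for the model,
the generator's assumptions and the design choices.

## Worked example

```r
library(lipolyzer)

# a synthetic 117-subject cohort with known truth, full pipeline
res <- run_pipeline(cohort_config(seed = 1), bootstrap_B = 1000, seed = 1)

res$effective_tests
#> Effective tests: 72 of 94 variables (99.5% variance); alpha 0.05 -> 0.000694

nmr <- res$forest[res$forest$family == "nmr", ]
head(nmr[order(-nmr$r2_insample),
         c("predictor", "beta", "ci_low", "ci_high", "p_raw",
           "r2_insample", "significant")], 5)
#>    predictor   beta  ci_low ci_high    p_raw r2_insample significant
#>   PUFA_ratio -0.175 -0.2723 -0.0776 6.66e-09        25.4        TRUE
#>  TG_PG_ratio  0.164  0.0642  0.2630 7.85e-08        22.3        TRUE
#>     LA_ratio -0.162 -0.2619 -0.0626 1.04e-07        21.9        TRUE
#>       VLDL_D  0.156  0.0556  0.2569 3.42e-07        20.3        TRUE
#>   XXL_VLDL_C  0.155  0.0544  0.2560 4.22e-07        20.0        TRUE
```

The generator's true effects act through the VLDL-diameter and
HDL-diameter variables (+0.2 and −0.15 uJ/s per SD). The top of the
forest table is the expected picture under that truth: the VLDL-size
block — diameter, triglyceride/phosphoglyceride ratio, the fatty-acid
saturation ratios that load on the same latent factor — dominates, with
effects of ~0.16 uJ/s per SD and corrected CIs (here at the
1 − 0.05/72 level) excluding zero. Effect signs follow the loadings:
variables anti-correlated with VLDL size (PUFA and linoleic-acid ratios)
show negative betas of the same magnitude.

```r
# extracting one activity from a simulated thermogram
tg <- generate_thermogram(0.72, noise_sd = 0.01, seed = 1)
activity_from_thermogram(tg)
#> LPL activity: 0.721 uJ/s (raw); linearity r2 = 1.000
```

The known baseline shift of 0.72 uJ/s (the cohort-mean activity) is
recovered to ~0.001 uJ/s under realistic noise, and the three injections
pass the linearity control (shifts in ratio 1 : 1.98 : 2.93, matching
the dilution arithmetic).

Regulator screening in the same run (`res$forest`, `family ==
"regulator"`) reports per-unit effects with the 0.05/9 threshold; under
the generator's defaults the regulators carry no true effect, so
significance flags there are calibrated false positives (about one
cohort in twenty shows one, as the family-wise rate intends).

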