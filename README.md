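# impulsim

Simulation and analysis tools for studying how questionnaire and behavioral
**impulsivity** measures predict **adolescent substance-use initiation** — a
rare binary outcome (~3.3% by mid-adolescence in community cohorts) — and
perceived harm of substances, in large multi-site cohorts with matched
discovery/validation arms.

The package is aimed at developmental and substance-use researchers who need
to (a) prototype and validate this analysis chain under a *known* generating
truth before touching restricted-access cohort data, and (b) answer design
questions: what sample size, and what outcome base rate, does it take for
effects of realistic size (odds ratios ≈ 1.2 per SD) to be detectable and
replicable?

## What it implements

* **Synthetic multi-site cohorts** (`simulate_cohort`): a Gaussian copula
  with Kendall-τ targets (ρ = sin(πτ/2)) and skewed marginals reproduces the
  measured correlation structure of questionnaire (UPPS-P, BIS/BAS, CBCL
  externalizing) and behavioral (delay discounting ln(k), SSRT, flanker)
  impulsivity; 22 sites, a stratified two-arm split, a calibrated rare
  initiation outcome with carry-forward across years, bounded perceived-harm
  totals (0–9; 0–15 for nicotine), and MAR/MCAR missingness. The generating
  truth is attached to every cohort.
* **Multiple imputation** (`pmm_impute`, `rubin_pool`, `pool_fits`):
  chained-equations predictive mean matching; Rubin's rules
  T = W + (1 + 1/m)B.
* **Correlation analysis** (`correlate_measures`): Kendall τ-b with
  Benjamini–Hochberg adjustment and a preregistered effect-size bound
  (|τ| > 0.08, or its r-equivalent conversion τ* = (2/π)·asin(0.08) ≈ 0.051).
* **Prediction models** (`fit_initiation_model`, `fit_harm_model`):
  ridge-penalized multilevel logistic/binomial regression with site-varying
  intercepts (penalized IRLS with a PQL-type variance update), odds-ratio and
  change-in-percent-total effect sizes, and discovery/validation
  `replication_flags`.
* **Out-of-sample evaluation** (`compare_predictor_sets`, `auc`,
  `delong_compare`, `ppv_recall`, `median_split_auc`, `kfold_cv`): AUC with
  DeLong intervals, pairwise DeLong comparison of the nested predictor-set
  models (A demographics, A+B questionnaires, A+C behavioral, A+B+C), PPV and
  recall, MSE, and 10-fold CV.
* **Power analysis** (`run_power_grid`, `summarize_power`): Monte Carlo power
  over sample-size × base-rate grids (default 3.3% vs 50%) for two criteria —
  within-sample odds-ratio significance and out-of-sample AUC improvement
  over an intercept-only model by DeLong's test.
* **Orchestration** (`run_pipeline`): runs all stages end to end, writing
  plain CSV/JSON outputs and a checksummed manifest; reruns with the same
  seed are byte-identical.

See the methods vignette (`vignettes/impulsim-methods.Rmd`) for the models,
assumptions, parameter defaults and design decisions.

## Worked example

```r
library(impulsim)

ch <- simulate_cohort(cohort_config(n = 4000), seed = 42)
mean(ch$initiation, na.rm = TRUE)
#> [1] 0.0373

disc <- ch[ch$arm == "discovery", ]
cc <- disc[complete.cases(disc[, set_predictors(c("B", "C"))]), ]
correlate_measures(cc)
#> Kendall tau-b correlations among 12 measures (threshold 0.080 on tau scale -> |tau| > 0.080)
#> Block mean |tau|:
#>         cross_method    within_behavioral within_questionnaire
#>                0.038                0.053                0.125

imp <- pmm_impute(disc, m = 2, iterations = 5, seed = 1)
fit <- fit_initiation_model(imp$completed[[1]])
effect_sizes(fit, arm = "discovery")  # selected rows
#>     predictor estimate    lo   hi       p  p_adj       arm
#> 1         age    1.519 1.175 1.96 0.00143 0.0275 discovery
#> 12 upps_per_b    1.465 1.142 1.88 0.00262 0.0275 discovery
#> 18 cbcl_ext_b    1.372 1.094 1.72 0.00629 0.0440 discovery
#> 21  flanker_b    0.774 0.595 1.01 0.05645 0.1694 discovery
```

The initiation rate lands on the calibrated 3.3% target (up to binomial
noise at n = 4,000). The correlation blocks show the structural pattern the
generator encodes: within-questionnaire mean |τ| well above the 0.08
threshold, cross-method and within-behavioral means below it. In the fitted
full model, the questionnaire measures carrying generating signal (CBCL
externalizing, UPPS lack of perseverance) and age come out with odds ratios
above 1 and small adjusted p-values, while the behavioral flanker score —
whose generating coefficient is zero — does not survive adjustment. At this
modest n the point estimates are noisy (the CBCL truth is OR 1.21 per SD);
the power machinery quantifies exactly this.

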