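---
title: "Simulating and analysing impulsivity-based prediction of adolescent substance-use initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing impulsivity-based prediction of adolescent substance-use initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Impulsivity is measured in two largely disjoint ways in developmental cohorts:
questionnaires (UPPS-P subscales, BIS/BAS, the CBCL externalizing subscale)
and behavioral tasks (delay discounting, the stop-signal task, the flanker
task). In large multi-site adolescent cohorts the two families correlate only
weakly with each other, and the interesting applied questions are (a) which
family, if either, predicts substance-use initiation — a *rare* binary outcome
(around 3.3% by mid-adolescence in community samples) — and perceived harm of
substances, and (b) what sample sizes and outcome base rates are needed for
such small effects (odds ratios around 1.2 per SD) to be detectable and
replicable.

`impulsim` implements that full analysis chain as reusable, tested components:

1. a synthetic multi-site cohort generator with controlled Kendall-τ
   correlation structure, skewed marginals, a calibrated rare outcome,
   bounded harm totals, and missingness;
2. multiple imputation by predictive mean matching with Rubin's-rules pooling;
3. Kendall τ-b correlation matrices with Benjamini–Hochberg adjustment and a
   preregistered effect-size threshold;
4. penalized multilevel logistic/binomial prediction models with
   discovery/validation replication flags;
5. out-of-sample evaluation by AUC with DeLong uncertainty and model
   comparison, PPV/recall, MSE, median-split AUC and 10-fold CV;
6. a Monte Carlo power framework over sample-size and base-rate grids.

Real restricted-access cohort data (such as the ABCD Study release this
design emulates) is deliberately *not* an input: the generator stands in for
it, with the generating truth recorded alongside every cohort so that every
downstream estimate can be checked against a known answer.

## The cohort generator

### Dependence: a Gaussian copula on the Kendall scale

The applied literature reports dependence among impulsivity measures as
Kendall's τ, but gives no generative mechanism. We induce dependence with a
Gaussian copula: a latent multivariate normal with Pearson correlation
$\rho = \sin(\pi\tau/2)$ (Greiner's relation), mapped through probability
integral transforms to each variable's marginal. Because Kendall's τ is
invariant under strictly monotone transforms, the sample τ converges to the
target for arbitrary continuous marginals — the generator hits τ targets
*exactly in distribution*, which is the reason for working on the copula
scale rather than specifying Pearson correlations of the observed scores.
Targets whose implied Pearson matrix is not positive semi-definite are
repaired by nearest-PSD projection (`Matrix::nearPD`) with a warning.

The default τ matrix encodes the qualitative structure seen in multi-site
adolescent data: within-UPPS pairs 0.05–0.38, within-BAS 0.30–0.35,
cross-questionnaire 0.01–0.22 peaking at BAS fun-seeking × UPPS
sensation-seeking (0.22), and behavioral-vs-anything below |0.08|. The
matrix lives in `cohort_config()`, not in code, and is fully overridable.

### Marginals

Questionnaire scores are positively skewed in this age range; the defaults
use gamma quantile transforms (shape 1.5–5). Delay-discounting ln(k) and the
flanker score are near-normal; SSRT is a mildly right-skewed shifted gamma
around ~280 ms. Only the skew *sign* and support are scientifically
constrained; the particular shapes are package defaults, stated here so that
users know what "realistic" means in the tests.

### Outcome, harm scores, sites, arms

Initiation is drawn from a multilevel logistic model
$y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + u_{s(i)} + x_i'\beta))$,
$u_s \sim N(0, \sigma_s^2)$ over 22 sites with mildly unequal sizes. The
intercept is *calibrated*: `calibrate_intercept()` root-finds $\beta_0$ on
[-50, 50] log-odds so the realized mean risk (including realized covariate
and site effects) equals the target rate — the same mechanism the power
framework uses to switch between a 3.3% and a 50% base rate. Yearly
indicators follow a cumulative profile rising from ~0.9% at baseline to the
full rate by year 3, with once-initiated-always-initiated carry-forward.

Default generating coefficients (per SD, log-odds): CBCL-E ln(1.21) and UPPS
(lack of) perseverance ln(1.24) — the two largest replicated questionnaire
effects reported for this design — plus small positive contributions from
premeditation, sensation seeking and BAS fun-seeking; *behavioral
coefficients are exactly zero*, so the generator embodies the
questionnaire-only-signal condition that the qualitative acceptance checks
probe. Demographics carry an age effect as the dominant Set-A predictor.

Perceived-harm totals are binomial counts on a logit-linear predictor:
$\mathrm{Binomial}(9, \mathrm{logit}^{-1}(\eta_i))$ per substance (15 trials
for nicotine, which has two extra items), guaranteeing the bounded 0–9/0–15
support by construction.

The discovery/validation split is stratified on site × sex with per-stratum
counts differing by at most one, emulating a pre-established matched-samples
design; whether the original matching used further variables is not
documented, so we stratify on these two only.

### Missingness

No missingness rates or mechanism are published for the real data, so the
defaults are explicit assumptions: MAR driven by observed age and parental
education (log-odds −0.6 and −0.4 per SD respectively, intercept calibrated
per column), 8% on questionnaire scores, 15% on task scores, 2% on the
outcome, 8% on harm totals. MCAR is available as a switch.

## Imputation and pooling

`pmm_impute()` is chained-equations predictive mean matching: each
incomplete column is regressed on all other columns (covariates *and*
outcomes), coefficients receive a Bayesian draw, and each missing cell takes
the observed value of one of `k_donors = 5` nearest neighbors in
predicted-value space. Donor matching preserves observed support exactly, so
binary/ordinal columns never receive impossible values; this is also why a
single working linear model per column suffices across types. Defaults
`m = 5`, 10 sweeps, conventional for this family of methods; the sweep order
(least-missing first) is recorded in the result.

`rubin_pool()` implements the standard combination rules
$\bar Q = m^{-1}\sum Q_j$, $W = m^{-1}\sum U_j$, $B = \mathrm{var}(Q_j)$,
$T = W + (1 + 1/m)B$, with the large-sample degrees of freedom
$(m-1)(1 + W/((1+1/m)B))^2$. AUCs are pooled by averaging per-imputation
AUCs and taking the median DeLong p across imputations — a pragmatic choice
where no standard exists.

## Correlations and the preregistered threshold

`correlate_measures()` uses τ-b (tie-corrected; questionnaire subscales are
ordinal with heavy ties) with BH adjustment over the unique pairs. The
preregistered effect-size bound of a bivariate r-equivalent of 0.08 is
ambiguous between two scales: applied to |τ| directly (the heatmap
convention) or converted to the τ whose r-equivalent is 0.08,
$\tau^* = (2/\pi)\arcsin(0.08) \approx 0.051$. Both are implemented;
`scale = "tau"` is the default and the conversion is one argument away. A
pair is flagged only when BH-adjusted p < 0.05 **and** |τ| exceeds the
bound. The result also reports block mean |τ| for within-questionnaire,
within-behavioral and cross-method groups, which is the level at which the
qualitative contrast (questionnaire blocks above threshold, cross-method
below) is stable — individual within-questionnaire pairs can sit below 0.08
by design.

## Penalized multilevel prediction models

The initiation model is logistic, the harm model binomial with the score as
`denominator` trials; both carry a site-varying intercept. "Penalized
maximum likelihood" is implemented as a quadratic (ridge / normal-prior)
penalty $\|\beta\|^2 / (2 \cdot 2.5^2)$ on standardized fixed effects — a
weakly informative default that guarantees finite estimates under separation
and rare outcomes; the intercept is unpenalized. Site intercepts enter as
ridge-penalized site indicators with penalty $1/\sigma_s^2$ (the classical
random-effect ↔ generalized-ridge identity), and $\sigma_s^2$ is estimated
by a penalized-quasi-likelihood-type update
$\sigma_s^2 \leftarrow (\sum_s u_s^2 + \mathrm{tr}\,A_{ss})/S$ where $A$ is
the inverse penalized information; a collapsed estimate (below $10^{-4}$ SD)
is reported as zero with near-fixed offsets. The fitting core is
iteratively reweighted least squares, which keeps a full multilevel refit
cheap enough to sit inside a Monte Carlo power loop (milliseconds at
n = 2,000). Weak-penalty fits agree with Laplace ML (`glmmTMB`) in the test
suite.

Continuous predictors are z-scored on the fitting (discovery) arm and the
same transform is applied to validation rows — standardizing each arm
separately would leak distributional information across the split.

Effect sizes are odds ratios per SD (initiation) with Wald intervals, and
for harm the *change in percent total*: the average marginal effect
$100 \cdot \mathrm{mean}_i[\mu(\eta_i + \beta_j) - \mu(\eta_i)]$ in
percentage points of the maximum score per +1 SD, with the interval obtained
by pushing the Wald endpoints of $\beta_j$ through the same monotone map.
The percent-total scale is not formally defined in the applied literature;
this operationalization is the package's choice and is validated against a
finite-difference oracle. A predictor is *replicated* only when its effect
direction agrees across arms and BH-adjusted p < 0.05 in both.

## Evaluation

AUC is the Mann–Whitney statistic via midranks. DeLong intervals and model
comparisons use structural components (placement values); comparing a model
with itself, or any degenerate-variance pair, returns p = 1 by convention.
The harm outcome is dichotomized at the observed median (ties to the low
class — the convention is recorded in the output) and the continuous
predictions are scored against that split. PPV/recall default to a 0.5
probability threshold; because published PPV values below the base rate are
not reproducible under any better-than-chance classifier at that threshold,
a top-k (prevalence-quantile) rule is provided as an explicit alternative
rather than guessing an undocumented convention. 10-fold CV (outcome-
stratified, each row scored exactly once) verifies the split-half
comparisons; `k = n` gives exact leave-one-out.

One caveat surfaced by the test suite: the DeLong test is calibrated for
comparing two *prespecified* correlated score vectors with equal true AUC;
for strictly nested models whose extra coefficients are estimated to be
near zero it is conservative (rejection below α), a known property of the
test rather than a defect of this implementation. The null-calibration
checks therefore use an exchangeable two-model null, and the
AUC-improvement power criterion compares against an intercept-only model,
where the degenerate-constant convention keeps the test exact.

## The power framework

Each repetition resamples predictor rows with replacement from a source
cohort (keeping rows intact preserves skew, correlations and site
membership), simulates outcomes from a logistic generating model whose
coefficients default to the fixed effects of the full model fit to the
discovery arm, re-calibrates the intercept to the cell's base rate (3.3% or
50% by default), refits, and scores one of two criteria: Wald p < α for a
target predictor in the multivariate refit, or DeLong p < α for the fitted
model against an intercept-only model on an *independent* validation
resample. Repetitions default to 2,016, with 200 recommended for desk-scale
exploration; power comes with its binomial MC standard error, fit failures
are counted, and a cell with >2% failures is marked invalid. Multiple
imputation is not re-run inside the loop — resampled rows are complete by
construction and there is no indication the original procedure re-imputed
per repetition. `summarize_power()` interpolates the smallest n reaching
80% power and censors slices that never reach it. An analytic Wald
approximation (`analytic_power_wald()`) anchors the machinery to closed-form
expectations in the univariate case.

## Numerical choices and degenerate inputs

* Intercept calibration brackets on [-50, 50] log-odds and errors outside it.
* IRLS clamps fitted probabilities to $[10^{-10}, 1-10^{-10}]$; convergence
  is declared on a $10^{-7}$ coefficient change, with the site-SD outer loop
  stopping at $10^{-4}$.
* PMM requires at least `k_donors` observed values per incomplete column and
  refuses all-missing columns.
* Constant vectors are rejected by `kendall_tau()`; single-class labels by
  `auc()`; constant observed totals by `median_split_auc()`.
* Unseen sites at prediction time fall back to the population intercept with
  a message.
* Ties at the observed median go to the low class; both conventions differ
  on toy cases and the choice is recorded in the result object.

## Problem sizes in the test and acceptance runs

The shipped checks use the sizes the science requires while staying
desk-scale: generator fidelity and odds-ratio recovery at n = 50,000;
structural-pattern reproduction on the full-scale cohort (n = 11,527, arms
of ~5,760); type-I calibration with 500 repetitions at n = 2,000; power
grids over n ∈ {250, 500, 1000, 2000} at 200 repetitions. The
reporting-quality repetition count (2,016) is available by configuration.

## What the synthetic data does and does not show

The generator reproduces the *measured structure* of a multi-site adolescent
cohort — correlation pattern, skew, site heterogeneity, base rate, bounded
totals, missingness — but not its unmeasured reality: no longitudinal growth
in impulsivity, no item-level questionnaire structure, no race/ethnicity or
employment covariates, no informative (MNAR) missingness, and demographics
are generated independently of the impulsivity measures. Passing tests
therefore demonstrate that the *methods* behave correctly under known truth,
not that any particular real-data estimate is reproduced; real printed
estimates from restricted-access data are deliberately out of scope.
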