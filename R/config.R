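## Cohort schema and default study conditions.
##
## Measure naming: questionnaire (Set B) and behavioral (Set C) impulsivity
## scores carry a window suffix, "_b" for baseline (years 0-1) and "_c" for
## concurrent (years 2-3). Demographics (Set A) are window-free.

SETB_MEASURES <- c("upps_nu", "upps_pre", "upps_per", "upps_ss", "upps_pu",
                   "bas_dr", "bas_fs", "bas_rr", "cbcl_ext")
SETC_MEASURES <- c("ddt_lnk", "ssrt", "flanker")
SETA_VARS <- c("age", "sex", "sibling", "income", "parent_edu",
               "par_sub", "par_mh", "par_leg")

#' Predictor-set definitions
#'
#' Maps the study's predictor-set labels to cohort column names: Set A
#' demographics/family context, Set B questionnaire impulsivity (UPPS-P,
#' BIS/BAS, CBCL externalizing without substance items), Set C behavioral
#' impulsivity (delay-discounting ln(k), stop-signal reaction time, flanker).
#'
#' @param sets Character subset of `c("A", "B", "C")`.
#' @param window `"baseline"` (years 0-1) or `"concurrent"` (years 2-3);
#'   applies to sets B and C only.
#' @return Character vector of cohort column names.
#' @export
set_predictors <- function(sets = c("A", "B", "C"), window = "baseline") {
  sets <- match.arg(sets, c("A", "B", "C"), several.ok = TRUE)
  window <- match.arg(window, c("baseline", "concurrent"))
  suf <- if (window == "baseline") "_b" else "_c"
  out <- character(0)
  if ("A" %in% sets) out <- c(out, SETA_VARS)
  if ("B" %in% sets) out <- c(out, paste0(SETB_MEASURES, suf))
  if ("C" %in% sets) out <- c(out, paste0(SETC_MEASURES, suf))
  out
}

# Default Kendall-tau targets among the 12 impulsivity measures, encoding the
# observed structure qualitatively: small-to-moderate within-UPPS (0.05-0.38),
# within-BAS 0.30-0.35, modest cross-questionnaire correlations peaking at
# BAS fun-seeking x UPPS sensation-seeking (0.22), CBCL-E modestly related to
# urgency, and behavioral measures essentially uncorrelated with everything
# (|tau| < 0.08).
default_tau_matrix <- function() {
  v <- c(SETB_MEASURES, SETC_MEASURES)
  m <- diag(length(v))
  dimnames(m) <- list(v, v)
  set_tau <- function(a, b, val) {
    m[a, b] <<- val
    m[b, a] <<- val
  }
  # within UPPS
  set_tau("upps_nu", "upps_pre", 0.20); set_tau("upps_nu", "upps_per", 0.18)
  set_tau("upps_nu", "upps_ss", 0.12);  set_tau("upps_nu", "upps_pu", 0.38)
  set_tau("upps_pre", "upps_per", 0.30); set_tau("upps_pre", "upps_ss", 0.05)
  set_tau("upps_pre", "upps_pu", 0.18); set_tau("upps_per", "upps_ss", 0.06)
  set_tau("upps_per", "upps_pu", 0.15); set_tau("upps_ss", "upps_pu", 0.20)
  # within BAS
  set_tau("bas_dr", "bas_fs", 0.35); set_tau("bas_dr", "bas_rr", 0.30)
  set_tau("bas_fs", "bas_rr", 0.33)
  # cross-questionnaire (UPPS x BAS, CBCL-E)
  set_tau("bas_fs", "upps_ss", 0.22)   # highest cross-questionnaire pair
  set_tau("bas_dr", "upps_ss", 0.12); set_tau("bas_rr", "upps_ss", 0.08)
  set_tau("bas_fs", "upps_nu", 0.10); set_tau("bas_fs", "upps_pu", 0.12)
  set_tau("bas_dr", "upps_nu", 0.06); set_tau("bas_rr", "upps_nu", 0.03)
  set_tau("bas_dr", "upps_pre", 0.02); set_tau("bas_fs", "upps_pre", 0.05)
  set_tau("bas_rr", "upps_pre", 0.01); set_tau("bas_dr", "upps_pu", 0.08)
  set_tau("bas_rr", "upps_pu", 0.04); set_tau("bas_dr", "upps_per", 0.03)
  set_tau("bas_fs", "upps_per", 0.04); set_tau("bas_rr", "upps_per", 0.02)
  set_tau("cbcl_ext", "upps_nu", 0.18); set_tau("cbcl_ext", "upps_pu", 0.16)
  set_tau("cbcl_ext", "upps_pre", 0.10); set_tau("cbcl_ext", "upps_per", 0.10)
  set_tau("cbcl_ext", "upps_ss", 0.06)
  set_tau("cbcl_ext", "bas_dr", 0.08); set_tau("cbcl_ext", "bas_fs", 0.10)
  set_tau("cbcl_ext", "bas_rr", 0.05)
  # within behavioral: weak
  set_tau("ddt_lnk", "ssrt", 0.05); set_tau("ddt_lnk", "flanker", -0.04)
  set_tau("ssrt", "flanker", -0.06)
  # behavioral vs questionnaire: all below |0.08|
  for (b in SETC_MEASURES) {
    for (q in SETB_MEASURES) {
      set_tau(b, q, 0.03)
    }
  }
  set_tau("ddt_lnk", "upps_ss", 0.05); set_tau("ddt_lnk", "cbcl_ext", 0.05)
  set_tau("ssrt", "cbcl_ext", 0.04); set_tau("flanker", "upps_pre", -0.03)
  m
}

# Marginal specs: family is one of "gamma" (right-skewed continuous),
# "normal" (symmetric continuous), "ordinal" (bounded count via a binomial
# quantile transform). Questionnaire scores are positively skewed; delay
# discounting ln(k) and flanker are near-normal; SSRT mildly right-skewed.
default_marginals <- function() {
  g <- function(shape, rate, shift = 0) {
    list(family = "gamma", shape = shape, rate = rate, shift = shift)
  }
  nrm <- function(mean, sd) list(family = "normal", mean = mean, sd = sd)
  list(
    upps_nu  = g(3, 0.4),  upps_pre = g(4, 0.5), upps_per = g(4, 0.5),
    upps_ss  = g(3, 0.35), upps_pu  = g(2.5, 0.35),
    bas_dr   = g(3, 0.45), bas_fs   = g(4, 0.5), bas_rr   = g(5, 0.45),
    cbcl_ext = g(1.5, 0.25),
    ddt_lnk  = nrm(-4.0, 1.5),
    ssrt     = g(8, 0.05, shift = 120),  # ms; mildly right-skewed around ~280
    flanker  = nrm(95, 7.5)
  )
}

# Generating model for substance-use initiation by year 3: log-odds per
# standardized unit (continuous) or per category (binary dummies). Only
# questionnaire measures carry signal; behavioral coefficients are exactly 0.
default_initiation_model <- function() {
  beta <- c(
    age = 0.34, sex = 0.10, sibling_sibling = 0.00, sibling_twin = 0.00,
    income = -0.10, parent_edu = -0.05,
    par_sub = 0.18, par_mh = 0.10, par_leg = 0.10,
    upps_nu_b = 0.00, upps_pre_b = log(1.10), upps_per_b = log(1.24),
    upps_ss_b = 0.05, upps_pu_b = 0.00,
    bas_dr_b = 0.00, bas_fs_b = 0.05, bas_rr_b = 0.00,
    cbcl_ext_b = log(1.21),
    ddt_lnk_b = 0.00, ssrt_b = 0.00, flanker_b = 0.00
  )
  generating_model(beta = beta, beta0 = NA_real_, site_sd = 0.3,
                   target_rate = 0.033)
}

# Generating model for the year-3 perceived-harm proportion (logit scale):
# higher impulsivity and older age lower perceived harm; reward
# responsiveness slightly raises it.
default_harm_model <- function() {
  beta <- c(
    age = -0.15, sex = -0.05,
    upps_nu_c = -0.05, upps_pre_c = -0.10, upps_ss_c = -0.12,
    upps_pu_c = -0.04, bas_rr_c = 0.05, cbcl_ext_c = -0.08,
    ddt_lnk_c = -0.03
  )
  generating_model(beta = beta, beta0 = 0.95, site_sd = 0.1,
                   target_rate = NA_real_)
}

#' Construct a generating model
#'
#' Bundles the truth used to simulate outcomes: standardized log-odds
#' coefficients, an intercept (possibly `NA`, meaning "calibrate to
#' `target_rate`"), the SD of site-varying intercepts, and the marginal
#' outcome rate targeted by the calibration.
#'
#' @param beta Named numeric vector of log-odds coefficients per standardized
#'   predictor.
#' @param beta0 Intercept on the log-odds scale, or `NA` to calibrate.
#' @param site_sd Standard deviation of site intercepts (log-odds), `>= 0`.
#' @param target_rate Marginal outcome probability in (0, 1) (may be `NA` for
#'   models whose intercept is fixed).
#' @return An object of class `generating_model`.
#' @export
generating_model <- function(beta, beta0 = NA_real_, site_sd = 0,
                             target_rate = NA_real_) {
  if (any(!is.finite(beta))) stop_domain("`beta` must be finite")
  if (is.null(names(beta)) || any(names(beta) == "")) {
    stop_domain("`beta` must be fully named")
  }
  if (site_sd < 0) stop_domain("`site_sd` must be >= 0")
  if (!is.na(target_rate) && (target_rate <= 0 || target_rate >= 1)) {
    stop_domain("`target_rate` must be in (0, 1)")
  }
  structure(list(beta = beta, beta0 = beta0, site_sd = site_sd,
                 target_rate = target_rate),
            class = "generating_model")
}

#' Default configuration for the synthetic cohort generator
#'
#' The defaults emulate the multi-site ABCD-like study conditions the
#' downstream analysis assumes: 11,527 participants across 22 sites with
#' mildly unequal site sizes, a matched two-arm discovery/validation split,
#' positively skewed questionnaire scores with small within-questionnaire
#' Kendall correlations and near-zero questionnaire-vs-behavioral
#' correlations, a rare initiation outcome (3.3% by year 3, rising from 0.9%
#' at baseline), bounded perceived-harm totals (0-9; 0-15 for nicotine), and
#' missing-at-random missingness on measures and outcomes.
#'
#' @param n Number of participants.
#' @param n_sites Number of sites.
#' @param ... Named overrides for any configuration element.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 11527, n_sites = 22, ...) {
  site_w <- 0.7 + 0.6 * (seq_len(n_sites) %% 5) / 4  # mildly unequal
  cfg <- list(
    n = n,
    n_sites = n_sites,
    site_weights = site_w / sum(site_w),
    tau = default_tau_matrix(),
    marginals = default_marginals(),
    window_autocorr = 0.6,  # latent correlation between baseline/concurrent
    initiation_model = default_initiation_model(),
    # cumulative initiation by year 0..3 (fractions of target_rate)
    year_profile = c(0.27, 0.48, 0.73, 1.00),
    harm_model = default_harm_model(),
    harm_substances = c(alcohol = 9L, nicotine = 15L, cannabis = 9L),
    missingness = list(
      mechanism = "MAR",
      rates = c(
        stats::setNames(rep(0.08, length(SETB_MEASURES) * 2),
                        c(paste0(SETB_MEASURES, "_b"), paste0(SETB_MEASURES, "_c"))),
        stats::setNames(rep(0.15, length(SETC_MEASURES) * 2),
                        c(paste0(SETC_MEASURES, "_b"), paste0(SETC_MEASURES, "_c"))),
        c(initiation = 0.02, harm_alcohol = 0.08, harm_nicotine = 0.08,
          harm_cannabis = 0.08)
      )
    )
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (cfg$n < 2) stop_domain("`n` must be >= 2")
  class(cfg) <- "cohort_config"
  cfg
}
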