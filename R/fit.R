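## Penalized multilevel logistic / binomial regression.
##
## Model: g(mu_i) = beta0 + u_{site(i)} + x_i' beta with logit link, where the
## fixed effects on standardized predictors carry a quadratic (ridge /
## normal-prior) penalty 1/(2*scale^2) * ||beta||^2 and the site intercepts u
## are equivalent to ridge-penalized site indicators with penalty 1/site_sd^2
## (the classical random-intercept <-> generalized-ridge identity). The
## intercept is unpenalized. site_sd is estimated by a penalized
## quasi-likelihood-type update: sigma^2 <- (sum u_j^2 + trace of the site
## block of the inverse penalized information) / S. The penalty guarantees
## finite estimates under (quasi-)separation and rare outcomes.

#' Build a standardized design matrix for the prediction models
#'
#' Continuous predictors are z-scored; 0/1 indicators are left as-is; the
#' `sibling` factor is reference-coded (`single` reference) into
#' `sibling_sibling` and `sibling_twin`. When `stats` is supplied (from a
#' discovery-arm fit), its centers/scales are reused, so validation rows are
#' standardized with the discovery transform and no information leaks.
#'
#' @param data Cohort rows.
#' @param predictors Cohort column names (see [set_predictors()]).
#' @param stats Optional standardization statistics from a previous call.
#' @return List with `X` (numeric matrix) and `stats`.
#' @export
build_design <- function(data, predictors, stats = NULL) {
  cols <- list()
  for (v in predictors) {
    x <- data[[v]]
    if (is.null(x)) stop_domain("predictor not found: ", v)
    if (is.factor(x) || is.character(x)) {
      if (!is.factor(x)) x <- factor(x)
      # declared levels are kept even when absent from this subset, so
      # training and validation designs always align
      for (lv in levels(x)[-1]) {
        cols[[paste0(v, "_", lv)]] <- as.numeric(x == lv)
      }
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (is.null(stats)) {
    stats <- lapply(seq_len(ncol(X)), function(j) {
      x <- X[, j]
      ux <- unique(x[!is.na(x)])
      if (length(ux) <= 2 && all(ux %in% c(0, 1))) {
        list(center = 0, scale = 1)  # indicator: leave on its own scale
      } else {
        list(center = mean(x, na.rm = TRUE),
             scale = stats::sd(x, na.rm = TRUE))
      }
    })
    names(stats) <- colnames(X)
  }
  for (j in colnames(X)) {
    X[, j] <- (X[, j] - stats[[j]]$center) / stats[[j]]$scale
  }
  list(X = X, stats = stats)
}

#' Ridge-penalized multilevel binomial GLM
#'
#' Core fitting routine behind [fit_initiation_model()] and
#' [fit_harm_model()]. Maximizes the binomial log-likelihood minus a
#' quadratic penalty on the standardized fixed effects, with site-varying
#' intercepts, by iteratively reweighted least squares; the site-intercept SD
#' is estimated by an outer PQL-type variance update (a collapsed estimate is
#' reported as `site_sd = 0` with fixed near-zero offsets).
#'
#' @param y Successes (0/1 for logistic; counts for bounded totals).
#' @param X Standardized design matrix (no intercept column).
#' @param site Integer site index per row.
#' @param trials Number of trials per row (1 for logistic; the harm
#'   denominator otherwise).
#' @param penalty_scale Prior SD of standardized fixed effects; the ridge
#'   penalty is `1/penalty_scale^2`. Default 2.5 (weakly informative).
#' @param site_sd Fixed site-intercept SD; `NULL` (default) to estimate.
#' @param max_outer,max_irls,tol Iteration controls.
#' @return Object of class `penalized_glmm`: coefficients, SEs, Wald p,
#'   site effects and SD, convergence flag.
#' @export
fit_penalized_glmm <- function(y, X, site, trials = 1, penalty_scale = 2.5,
                               site_sd = NULL, max_outer = 15L,
                               max_irls = 50L, tol = 1e-7) {
  n <- length(y)
  trials <- rep_len(trials, n)
  if (any(y < 0 | y > trials)) stop_domain("outcome outside [0, trials]")
  S <- max(site)
  D <- matrix(0, n, S)
  D[cbind(seq_len(n), site)] <- 1
  Z <- cbind(`(Intercept)` = 1, X, D)
  p_fix <- ncol(X)
  idx_fix <- 1 + seq_len(p_fix)
  idx_site <- 1 + p_fix + seq_len(S)

  estimate_sd <- is.null(site_sd)
  sigma2 <- if (estimate_sd) 0.1 else max(site_sd^2, 1e-8)
  theta <- rep(0, ncol(Z))
  theta[1] <- logit(min(max(sum(y) / sum(trials), 1e-4), 1 - 1e-4))
  converged <- FALSE
  A <- NULL

  for (outer in seq_len(max_outer)) {
    pen <- c(0, rep(1 / penalty_scale^2, p_fix), rep(1 / sigma2, S))
    # IRLS at fixed penalty
    for (it in seq_len(max_irls)) {
      eta <- drop(Z %*% theta)
      mu <- invlogit(eta)
      mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      w <- trials * mu * (1 - mu)
      zresp <- eta + (y - trials * mu) / w
      H <- crossprod(Z, Z * w)
      diag(H) <- diag(H) + pen
      theta_new <- drop(solve(H, crossprod(Z, w * zresp)))
      delta <- max(abs(theta_new - theta))
      theta <- theta_new
      if (delta < tol) break
    }
    irls_converged <- delta < sqrt(tol)
    if (!estimate_sd) { converged <- irls_converged; break }
    A <- solve(H)
    u <- theta[idx_site]
    sigma2_new <- (sum(u^2) + sum(diag(A)[idx_site])) / S
    sigma2_new <- max(sigma2_new, 1e-8)
    if (abs(sqrt(sigma2_new) - sqrt(sigma2)) < 1e-4) {
      sigma2 <- sigma2_new
      converged <- irls_converged
      break
    }
    sigma2 <- sigma2_new
  }
  if (is.null(A)) {
    eta <- drop(Z %*% theta)
    mu <- pmin(pmax(invlogit(eta), 1e-10), 1 - 1e-10)
    w <- trials * mu * (1 - mu)
    H <- crossprod(Z, Z * w)
    diag(H) <- diag(H) + c(0, rep(1 / penalty_scale^2, p_fix), rep(1 / sigma2, S))
    A <- solve(H)
  }
  se <- sqrt(diag(A))
  coef_fixed <- theta[c(1, idx_fix)]
  names(coef_fixed) <- c("(Intercept)", colnames(X))
  se_fixed <- se[c(1, idx_fix)]
  names(se_fixed) <- names(coef_fixed)
  zval <- coef_fixed / se_fixed
  structure(list(
    coefficients = coef_fixed,
    se = se_fixed,
    z = zval,
    p = 2 * stats::pnorm(-abs(zval)),
    u_site = stats::setNames(theta[idx_site], paste0("site", seq_len(S))),
    site_sd = if (sigma2 <= 2e-8) 0 else sqrt(sigma2),
    penalty_scale = penalty_scale,
    converged = converged,
    n = n
  ), class = "penalized_glmm")
}

#' Fit the substance-use initiation model
#'
#' Penalized multilevel logistic regression of the binary initiation outcome
#' on the requested predictor sets, with a site-varying intercept. Continuous
#' predictors are z-scored on the fitting (discovery) data; supply
#' `standardize` to reuse a previous transform.
#'
#' @param data Cohort rows (typically one arm).
#' @param sets Predictor sets to include, subset of `c("A", "B", "C")`.
#' @param window `"baseline"` or `"concurrent"` measurement window for sets
#'   B/C.
#' @param outcome Outcome column name (default `"initiation"`).
#' @param penalty_scale Ridge prior SD for standardized fixed effects.
#' @param standardize Optional standardization stats from a discovery fit.
#' @param site_sd Optional fixed site SD (estimated when `NULL`).
#' @return Object of class `impulsim_fit`.
#' @export
fit_initiation_model <- function(data, sets = c("A", "B", "C"),
                                 window = "baseline", outcome = "initiation",
                                 penalty_scale = 2.5, standardize = NULL,
                                 site_sd = NULL) {
  predictors <- set_predictors(sets, window)
  y <- data[[outcome]]
  if (is.null(y)) stop_domain("outcome column not found: ", outcome)
  if (!all(stats::na.omit(y) %in% 0:1)) stop_domain("outcome must be binary 0/1")
  fit_model_internal(data, predictors, y, trials = 1, sets = sets,
                     window = window, outcome = outcome,
                     outcome_kind = "initiation",
                     penalty_scale = penalty_scale,
                     standardize = standardize, site_sd = site_sd)
}

#' Fit the perceived-harm model
#'
#' Penalized multilevel binomial regression (logit link) for the bounded
#' harm total, which accommodates the non-normal, bounded score: the outcome
#' is treated as `denominator` trials.
#'
#' @inheritParams fit_initiation_model
#' @param outcome Harm-total column (e.g. `"harm_alcohol"`).
#' @param denominator Maximum attainable total: 9, or 15 for nicotine.
#' @return Object of class `impulsim_fit`.
#' @export
fit_harm_model <- function(data, sets = c("A", "B", "C"),
                           window = "concurrent", outcome = "harm_alcohol",
                           denominator = 9, penalty_scale = 2.5,
                           standardize = NULL, site_sd = NULL) {
  y <- data[[outcome]]
  if (is.null(y)) stop_domain("outcome column not found: ", outcome)
  if (any(stats::na.omit(y) < 0) || any(stats::na.omit(y) > denominator)) {
    stop_domain("harm totals must lie in [0, ", denominator, "]")
  }
  predictors <- set_predictors(sets, window)
  fit_model_internal(data, predictors, y, trials = denominator, sets = sets,
                     window = window, outcome = outcome,
                     outcome_kind = "harm", penalty_scale = penalty_scale,
                     standardize = standardize, site_sd = site_sd)
}

fit_model_internal <- function(data, predictors, y, trials, sets, window,
                               outcome, outcome_kind, penalty_scale,
                               standardize, site_sd) {
  keep <- !is.na(y)
  des <- build_design(data, predictors, stats = standardize)
  cc <- keep & stats::complete.cases(des$X)
  if (!any(cc)) stop_domain("no complete rows to fit on")
  core <- fit_penalized_glmm(y[cc], des$X[cc, , drop = FALSE],
                             site = data$site[cc], trials = trials,
                             penalty_scale = penalty_scale, site_sd = site_sd)
  structure(list(
    core = core,
    predictors = predictors,
    design_names = colnames(des$X),
    standardize = des$stats,
    sets = sets, window = window,
    outcome = outcome, outcome_kind = outcome_kind,
    trials = trials,
    n_used = sum(cc)
  ), class = "impulsim_fit")
}

#' @export
coef.impulsim_fit <- function(object, ...) object$core$coefficients

#' @export
print.impulsim_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized multilevel %s model (%s window): n = %d, sites sd = %.3f%s\n",
    x$outcome_kind, x$window, x$n_used, x$core$site_sd,
    if (x$core$converged) "" else " [NOT CONVERGED]"))
  print(round(cbind(estimate = x$core$coefficients, se = x$core$se,
                    p = x$core$p), 4))
  invisible(x)
}

#' Per-predictor effect sizes from a fitted model
#'
#' For initiation models, effects are odds ratios per standardized unit with
#' Wald 95% intervals. For harm models, the effect is the change in percent
#' of the maximum total per +1 SD of the predictor — the average marginal
#' effect `100 * mean_i[ plogis(eta_i + beta_j) - plogis(eta_i) ]`, with the
#' interval obtained by propagating the Wald interval of `beta_j` through the
#' same (monotone) map. P-values are Benjamini-Hochberg adjusted across the
#' reported predictors.
#'
#' @param fit An `impulsim_fit`.
#' @param data Rows used to average the marginal effect (harm models);
#'   defaults to refusing if missing for harm fits.
#' @param arm Optional arm label recorded in the output.
#' @return Data.frame: predictor, estimate, lo, hi, p, p_adj, arm.
#' @export
effect_sizes <- function(fit, data = NULL, arm = NA_character_) {
  stopifnot(inherits(fit, "impulsim_fit"))
  b <- fit$core$coefficients[-1]
  se <- fit$core$se[-1]
  p <- fit$core$p[-1]
  lo <- b - stats::qnorm(0.975) * se
  hi <- b + stats::qnorm(0.975) * se
  if (fit$outcome_kind == "initiation") {
    est <- exp(b); lo <- exp(lo); hi <- exp(hi)
  } else {
    if (is.null(data)) stop_domain("harm effect sizes need `data` to average over")
    des <- build_design(data, fit$predictors, stats = fit$standardize)
    ok <- stats::complete.cases(des$X)
    eta <- drop(cbind(1, des$X[ok, , drop = FALSE]) %*% fit$core$coefficients) +
      site_effect(fit, data$site[ok])
    ame <- function(bj) 100 * mean(invlogit(eta + bj) - invlogit(eta))
    est <- vapply(b, ame, numeric(1))
    lo <- vapply(lo, ame, numeric(1))
    hi <- vapply(hi, ame, numeric(1))
  }
  data.frame(
    predictor = names(b),
    estimate = unname(est), lo = unname(lo), hi = unname(hi),
    p = unname(p),
    p_adj = unname(bh_adjust(p)),
    arm = arm,
    row.names = NULL
  )
}

site_effect <- function(fit, site) {
  u <- fit$core$u_site
  out <- rep(0, length(site))
  known <- site >= 1 & site <= length(u)
  out[known] <- u[site[known]]
  out
}

#' Discovery/validation replication flags
#'
#' A predictor's effect is flagged as replicated only if its direction agrees
#' across the discovery and validation arms and its BH-adjusted p-value is
#' below `alpha` in both.
#'
#' @param discovery,validation Effect tables from [effect_sizes()] with the
#'   same predictors (any order).
#' @param alpha Significance level (default 0.05).
#' @param null_value Effect value representing "no effect" (1 for odds
#'   ratios, 0 for percent-change effects); inferred from the data when
#'   `NULL` is impossible, so pass explicitly for odds ratios if unclear.
#' @return The discovery table with columns `validation_estimate`,
#'   `validation_p_adj` and logical `replicated`.
#' @export
replication_flags <- function(discovery, validation, alpha = 0.05,
                              null_value = NULL) {
  if (!setequal(discovery$predictor, validation$predictor)) {
    stop_domain("discovery and validation tables list different predictors")
  }
  validation <- validation[match(discovery$predictor, validation$predictor), ]
  if (is.null(null_value)) {
    # odds ratios are strictly positive; percent changes straddle 0
    null_value <- if (all(c(discovery$estimate, validation$estimate) > 0)) 1 else 0
  }
  same_dir <- sign(discovery$estimate - null_value) ==
    sign(validation$estimate - null_value)
  out <- discovery
  out$validation_estimate <- validation$estimate
  out$validation_p_adj <- validation$p_adj
  out$replicated <- same_dir & discovery$p_adj < alpha & validation$p_adj < alpha
  out
}
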