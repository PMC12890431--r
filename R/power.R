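## Monte Carlo power framework: resample predictors with replacement from a
## source cohort (preserving the empirical joint distribution, skew and
## correlations), simulate outcomes from a calibrated logistic generating
## model, refit, and estimate power across sample sizes and base rates for
## two criteria: (a) within-sample Wald significance of a target predictor's
## odds ratio, and (b) a significant out-of-sample AUC enhancement over an
## intercept-only model by DeLong's test.

#' Power-simulation configuration
#'
#' @param n_grid Strictly increasing sample sizes.
#' @param base_rates Outcome base rates (default the observed rare rate 0.033
#'   and a balanced 0.5, the enriched-sample scenario).
#' @param reps Monte Carlo repetitions per grid cell (default 2016;
#'   reporting-quality runs should keep `reps >= 100`).
#' @param alpha Significance level.
#' @param criterion `"odds_ratio"` (Wald p of the target predictor in the
#'   refit model) or `"auc_improvement"` (DeLong p of the fitted model vs an
#'   intercept-only model on an independent simulated validation resample).
#' @param scope `"multivariate"` (refit the full model) or `"single"`
#'   (reduced model with only the target measure, plus intercept).
#' @param seed Master seed.
#' @return List of class `power_config`.
#' @export
power_config <- function(n_grid = c(250, 500, 1000, 2000),
                         base_rates = c(0.033, 0.5),
                         reps = 2016L, alpha = 0.05,
                         criterion = c("odds_ratio", "auc_improvement"),
                         scope = c("multivariate", "single"),
                         seed = 1L) {
  criterion <- match.arg(criterion)
  scope <- match.arg(scope)
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop_domain("`n_grid` must be strictly increasing")
  }
  if (alpha <= 0 || alpha >= 1) stop_domain("`alpha` must be in (0, 1)")
  structure(list(n_grid = n_grid, base_rates = base_rates, reps = as.integer(reps),
                 alpha = alpha, criterion = criterion, scope = scope,
                 seed = seed),
            class = "power_config")
}

#' Resample predictor rows with replacement
#'
#' Rows are kept intact, preserving the empirical joint distribution of the
#' source cohort (skewness, correlations, site membership).
#'
#' @param source Source data.frame (non-empty).
#' @param n Number of rows to draw.
#' @param seed Integer seed.
#' @return Data.frame of `n` resampled rows.
#' @export
resample_predictors <- function(source, n, seed = NULL) {
  if (nrow(source) == 0) stop_domain("source table is empty")
  with_seed(seed, source[sample.int(nrow(source), n, replace = TRUE), ,
                         drop = FALSE])
}

#' Simulate outcomes for resampled predictors at a given base rate
#'
#' Uses the generating model's coefficients (typically the fixed-effect
#' estimates of a model fit to the discovery arm), re-calibrates the
#' intercept so the mean risk over the supplied rows equals `base_rate`, and
#' draws Bernoulli outcomes.
#'
#' @param data Resampled predictor rows.
#' @param model A [generating_model()] (its `target_rate` is overridden by
#'   `base_rate`).
#' @param base_rate Target marginal outcome probability.
#' @param seed Integer seed.
#' @return Integer 0/1 outcomes with attribute `beta0`.
#' @export
simulate_outcome <- function(data, model, base_rate, seed = NULL) {
  m <- generating_model(beta = model$beta, beta0 = NA_real_,
                        site_sd = 0, target_rate = base_rate)
  generate_initiation(data, m, site = data$site, seed = seed)
}

#' Extract a generating model from a fitted initiation model
#'
#' Mirrors the power framework's use of discovery-fit fixed effects as the
#' generating truth.
#'
#' @param fit An `impulsim_fit` for the initiation outcome.
#' @param drop_intercept Leave the intercept free for base-rate calibration
#'   (default).
#' @return A [generating_model()] on the fit's design-column names.
#' @export
generating_model_from_fit <- function(fit, drop_intercept = TRUE) {
  b <- fit$core$coefficients
  generating_model(beta = b[setdiff(names(b), "(Intercept)")],
                   beta0 = if (drop_intercept) NA_real_ else b[["(Intercept)"]],
                   site_sd = 0, target_rate = NA_real_)
}

#' Run the Monte Carlo power grid
#'
#' For every cell (measure x n x base rate) and repetition: resample `n`
#' predictor rows, simulate outcomes from the generating model calibrated to
#' the cell's base rate, refit, and score the criterion. The power estimate
#' is the fraction of repetitions with a significant result, with its
#' binomial Monte Carlo standard error. Fit failures are logged and counted;
#' a cell with more than 2% failures is marked invalid.
#'
#' Generating betas are expressed on design-column names; `measures` maps a
#' display name to the design column(s) tested (criterion `"odds_ratio"`
#' tests the first column's Wald p in the refit model; criterion
#' `"auc_improvement"` scores the model named by the measure — use
#' `"full"` mapped to `NULL` for the all-predictor model).
#'
#' @param config A [power_config()].
#' @param source Source cohort rows to resample predictors from.
#' @param model A [generating_model()] holding the generating coefficients.
#' @param measures Named list: measure label -> design column(s); `NULL`
#'   entry means the full model.
#' @param window,sets Model specification used for refits.
#' @param penalty_scale Ridge scale for refits (same contract as
#'   [fit_initiation_model()]).
#' @return Data.frame of class `power_grid`: measure, n, base_rate,
#'   criterion, power, mc_se, reps, failures, valid.
#' @export
run_power_grid <- function(config, source, model,
                           measures = list(cbcl_ext = "cbcl_ext_b"),
                           sets = c("A", "B", "C"), window = "baseline",
                           penalty_scale = 2.5) {
  stopifnot(inherits(config, "power_config"), inherits(model, "generating_model"))
  grid <- expand.grid(measure = names(measures), n = config$n_grid,
                      base_rate = config$base_rates,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    run_power_cell(config, source, model, grid$measure[g],
                   measures[[grid$measure[g]]], grid$n[g], grid$base_rate[g],
                   sets, window, penalty_scale,
                   cell_seed = derive_seed(config$seed, g))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_grid", "data.frame")
  out
}

run_power_cell <- function(config, source, model, measure, target_cols, n,
                           base_rate, sets, window, penalty_scale, cell_seed) {
  hits <- 0L
  failures <- 0L
  for (r in seq_len(config$reps)) {
    seed_r <- derive_seed(cell_seed, r)
    res <- tryCatch(
      power_one_rep(config, source, model, target_cols, n, base_rate,
                    sets, window, penalty_scale, seed_r),
      error = function(e) NA
    )
    if (is.na(res)) failures <- failures + 1L else hits <- hits + res
  }
  used <- config$reps - failures
  power <- if (used > 0) hits / used else NA_real_
  data.frame(
    measure = measure, n = n, base_rate = base_rate,
    criterion = config$criterion, power = power,
    mc_se = if (used > 0) sqrt(power * (1 - power) / used) else NA_real_,
    reps = config$reps, failures = failures,
    valid = failures <= 0.02 * config$reps
  )
}

power_one_rep <- function(config, source, model, target_cols, n, base_rate,
                          sets, window, penalty_scale, seed_r) {
  disc <- resample_predictors(source, n, seed = derive_seed(seed_r, 1))
  disc$.y <- as.integer(simulate_outcome(disc, model, base_rate,
                                         seed = derive_seed(seed_r, 2)))
  if (sum(disc$.y) < 2 || sum(disc$.y) > n - 2) return(NA)

  if (config$criterion == "odds_ratio") {
    fit <- if (config$scope == "multivariate") {
      fit_initiation_model(disc, sets = sets, window = window, outcome = ".y",
                           penalty_scale = penalty_scale)
    } else {
      fit_single_measure(disc, target_cols, ".y", penalty_scale)
    }
    return(as.integer(fit$core$p[[target_cols[1]]] < config$alpha))
  }

  # AUC-improvement criterion: independent validation resample, DeLong of the
  # fitted model's scores against an intercept-only (constant) model.
  fit <- if (is.null(target_cols)) {
    fit_initiation_model(disc, sets = sets, window = window, outcome = ".y",
                         penalty_scale = penalty_scale)
  } else {
    fit_single_measure(disc, target_cols, ".y", penalty_scale)
  }
  val <- resample_predictors(source, n, seed = derive_seed(seed_r, 3))
  val$.y <- as.integer(simulate_outcome(val, model, base_rate,
                                        seed = derive_seed(seed_r, 4)))
  if (sum(val$.y) < 2 || sum(val$.y) > n - 2) return(NA)
  s <- predict_out_of_sample(fit, val)
  ok <- !is.na(s)
  cmp <- delong_compare(s[ok], rep(0.5, sum(ok)), val$.y[ok])
  as.integer(cmp$p < config$alpha)
}

# Reduced model: intercept + site + a single measure's design column(s).
fit_single_measure <- function(data, target_cols, outcome, penalty_scale) {
  src <- unique(sub("^sibling_.*$", "sibling", target_cols))
  fit_model_internal(data, src, data[[outcome]], trials = 1, sets = NULL,
                     window = NA_character_, outcome = outcome,
                     outcome_kind = "initiation",
                     penalty_scale = penalty_scale, standardize = NULL,
                     site_sd = NULL)
}

#' Minimum sample size reaching a target power
#'
#' For each measure-by-base-rate slice of a power grid, reports the smallest
#' sample size reaching `target` power, interpolating linearly between the
#' bracketing grid points; slices never reaching the target are censored
#' (`NA` with `reached = FALSE`).
#'
#' @param grid Output of [run_power_grid()].
#' @param target Target power (default 0.8).
#' @return Data.frame: measure, base_rate, criterion, n_min, reached.
#' @export
summarize_power <- function(grid, target = 0.8) {
  split_by <- interaction(grid$measure, grid$base_rate, grid$criterion,
                          drop = TRUE)
  rows <- lapply(split(grid, split_by), function(d) {
    d <- d[order(d$n), ]
    res <- data.frame(measure = d$measure[1], base_rate = d$base_rate[1],
                      criterion = d$criterion[1], n_min = NA_real_,
                      reached = FALSE)
    idx <- which(d$power >= target)
    if (length(idx)) {
      i <- idx[1]
      res$reached <- TRUE
      if (i == 1) {
        res$n_min <- d$n[1]
      } else {
        p0 <- d$power[i - 1]; p1 <- d$power[i]
        res$n_min <- d$n[i - 1] + (target - p0) / (p1 - p0) * (d$n[i] - d$n[i - 1])
      }
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analytic Wald power approximation for a univariate logistic model
#'
#' Large-sample check used to validate the simulation machinery: for a single
#' standardized normal predictor with log-odds slope `beta` and outcome rate
#' `pi`, `Var(beta_hat) ~ 1/(n pi (1-pi))` and power is
#' `Phi(|beta| sqrt(n pi (1-pi)) - z_{alpha/2})`.
#'
#' @param beta Log-odds slope per SD.
#' @param n Sample size.
#' @param rate Outcome base rate.
#' @param alpha Significance level.
#' @return Approximate power.
#' @export
analytic_power_wald <- function(beta, n, rate, alpha = 0.05) {
  se <- 1 / sqrt(n * rate * (1 - rate))
  stats::pnorm(abs(beta) / se - stats::qnorm(1 - alpha / 2))
}
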