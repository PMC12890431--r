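## Synthetic multi-site cohort generator.
##
## Dependence among impulsivity measures is induced by a Gaussian copula:
## latent multivariate normal Z with Pearson correlation sin(pi*tau/2), mapped
## through probability integral transforms to the configured marginals. This
## hits Kendall-tau targets exactly in distribution for continuous marginals,
## because tau is invariant under the strictly monotone quantile transforms.

marginal_quantile <- function(spec, u) {
  switch(spec$family,
    gamma = (spec$shift %||% 0) + stats::qgamma(u, shape = spec$shape, rate = spec$rate),
    normal = stats::qnorm(u, mean = spec$mean, sd = spec$sd),
    ordinal = stats::qbinom(u, size = spec$size, prob = spec$prob),
    stop_domain("unknown marginal family: ", spec$family)
  )
}

#' Generate correlated impulsivity covariates
#'
#' Draws `n` rows from a Gaussian copula at the latent Pearson correlation
#' implied by the Kendall-tau targets, then maps each column through its
#' marginal quantile function.
#'
#' @param n Number of rows (`>= 2`).
#' @param target A [corr_target()] (or plain tau matrix, converted on the fly).
#' @param marginals Named list of marginal specs (see [cohort_config()]).
#' @param seed Integer seed; equal seeds give identical tables.
#' @return A data.frame with one column per target variable.
#' @export
generate_covariates <- function(n, target, marginals, seed = NULL) {
  if (n < 2) stop_domain("`n` must be >= 2")
  if (!inherits(target, "corr_target")) target <- corr_target(target)
  with_seed(seed, {
    z <- draw_latent(n, target)
    latent_to_margins(z, marginals)
  })
}

draw_latent <- function(n, target) {
  L <- chol(target$rho + diag(1e-10, nrow(target$rho)))
  z <- matrix(stats::rnorm(n * nrow(target$rho)), nrow = n) %*% L
  colnames(z) <- target$variables
  z
}

latent_to_margins <- function(z, marginals) {
  out <- as.data.frame(z)
  for (v in colnames(z)) {
    spec <- marginals[[v]]
    if (is.null(spec)) stop_domain("no marginal spec for variable ", v)
    out[[v]] <- marginal_quantile(spec, stats::pnorm(z[, v]))
  }
  out
}

#' Calibrate a generating-model intercept to a target outcome rate
#'
#' Finds the log-odds intercept at which the mean of
#' `plogis(beta0 + eta_offset)` equals `target_rate`, by monotone root
#' bracketing on \[-50, 50\] (the mean risk is strictly increasing in the
#' intercept).
#'
#' @param eta_offset Numeric vector of per-row linear-predictor offsets
#'   (covariate effects plus any site effects), without the intercept.
#' @param target_rate Target marginal probability in (0, 1).
#' @param tolerance Convergence tolerance on the achieved rate.
#' @return The calibrated intercept (log-odds).
#' @export
#' @examples
#' calibrate_intercept(rep(0, 100), 0.5)  # 0
calibrate_intercept <- function(eta_offset, target_rate, tolerance = 1e-8) {
  if (length(eta_offset) == 0) stop_domain("`eta_offset` must be non-empty")
  if (target_rate <= 0 || target_rate >= 1) {
    stop_domain("`target_rate` must be in (0, 1)")
  }
  f <- function(b0) mean(invlogit(b0 + eta_offset)) - target_rate
  if (f(-50) > 0 || f(50) < 0) {
    stop("failed to bracket the target rate within [-50, 50] log-odds",
         call. = FALSE)
  }
  stats::uniroot(f, c(-50, 50), tol = tolerance)$root
}

# Linear predictor of a generating model on standardized covariates.
# Standardization: continuous columns are z-scored on the supplied data;
# 0/1 indicators and factor dummies enter as-is, matching how the fitted
# models standardize predictors.
generating_eta <- function(data, beta) {
  src <- sub("^sibling_.*$", "sibling", names(beta))
  X <- build_design(data, unique(src))$X
  missing_cols <- setdiff(names(beta), colnames(X))
  if (length(missing_cols)) {
    stop_domain("generating beta names absent from design: ",
                paste(missing_cols, collapse = ", "))
  }
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' Simulate a binary initiation outcome from a multilevel logistic model
#'
#' Draws `y_i ~ Bernoulli(plogis(beta0 + u_site(i) + x_i' beta))` with site
#' intercepts `u ~ N(0, site_sd^2)`. If the model's intercept is `NA` it is
#' calibrated so the achieved mean risk equals `target_rate`
#' (via [calibrate_intercept()], on the realized covariate and site effects).
#'
#' @param data Data.frame holding the generating covariates.
#' @param model A [generating_model()].
#' @param site Integer site index per row.
#' @param seed Integer seed.
#' @return Integer 0/1 vector with attributes `beta0` (intercept used) and
#'   `u_site` (the simulated site effects).
#' @export
generate_initiation <- function(data, model, site, seed = NULL) {
  stopifnot(inherits(model, "generating_model"))
  with_seed(seed, {
    eta_fixed <- generating_eta(data, model$beta)
    n_sites <- max(site)
    u <- stats::rnorm(n_sites, 0, model$site_sd)
    offset <- eta_fixed + u[site]
    beta0 <- if (is.na(model$beta0)) {
      calibrate_intercept(offset, model$target_rate)
    } else {
      model$beta0
    }
    y <- stats::rbinom(length(offset), 1L, invlogit(beta0 + offset))
    structure(y, beta0 = beta0, u_site = u)
  })
}

#' Simulate a bounded perceived-harm total
#'
#' Scores are binomial counts on a logit-linear predictor:
#' `score_i ~ Binomial(denominator, plogis(eta_i))`, giving integer totals in
#' `[0, denominator]` (9 for alcohol/cannabis; 15 for nicotine, which has two
#' extra items).
#'
#' @inheritParams generate_initiation
#' @param denominator Maximum attainable total, 9 or 15.
#' @param shift Additive log-odds shift (used to vary substances around one
#'   harm model).
#' @return Integer vector in `[0, denominator]`.
#' @export
generate_harm <- function(data, model, site, denominator = 9, shift = 0,
                          seed = NULL) {
  if (!denominator %in% c(9, 15)) {
    stop_domain("`denominator` must be 9 or 15")
  }
  stopifnot(inherits(model, "generating_model"))
  with_seed(seed, {
    eta <- model$beta0 + shift + generating_eta(data, model$beta)
    n_sites <- max(site)
    u <- stats::rnorm(n_sites, 0, model$site_sd)
    stats::rbinom(length(eta), denominator, invlogit(eta + u[site]))
  })
}

#' Carry initiation forward across assessment years
#'
#' Once a participant reports initiation in any wave, all later waves are
#' coded as initiated; missing waves are ignored when accumulating.
#'
#' @param x Matrix (rows = participants, columns = years in order) or vector
#'   of 0/1/NA yearly indicators.
#' @return Object of the same shape with cumulative indicators,
#'   non-decreasing across years.
#' @export
#' @examples
#' carry_forward_initiation(c(0, 0, 1, 0))   # 0 0 1 1
#' carry_forward_initiation(c(1, NA, 0, 0))  # 1 1 1 1
carry_forward_initiation <- function(x) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, carry_forward_initiation)))
  }
  out <- x
  seen <- 0L
  for (t in seq_along(x)) {
    if (!is.na(x[t]) && x[t] == 1) seen <- 1L
    out[t] <- if (seen == 1L) 1L else if (is.na(x[t])) NA_integer_ else 0L
    if (seen == 1L) out[t] <- 1L
  }
  out
}

#' Inject missingness into cohort columns
#'
#' Masks cells in the named columns at the requested rates, either completely
#' at random (MCAR) or at random given observed age and parental education
#' (MAR: the missingness log-odds increase with younger age and lower
#' parental education; the conditioning variables themselves are never
#' masked). Per-column intercepts are calibrated so realized missingness
#' matches the requested rate in expectation.
#'
#' @param data Cohort data.frame (must contain `age` and `parent_edu` for
#'   MAR).
#' @param rates Named vector of missingness probabilities in `[0, 1)`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed Integer seed.
#' @return `data` with `NA`s inserted; attribute `miss_mask` holds the
#'   logical mask (TRUE = masked).
#' @export
inject_missingness <- function(data, rates, mechanism = c("MAR", "MCAR"),
                               seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates >= 1)) stop_domain("rates must be in [0, 1)")
  bad <- setdiff(names(rates), names(data))
  if (length(bad)) stop_domain("unknown columns: ", paste(bad, collapse = ", "))
  if (mechanism == "MAR" && any(names(rates) %in% c("age", "parent_edu"))) {
    stop_domain("MAR conditioning variables (age, parent_edu) cannot be masked")
  }
  with_seed(seed, {
    mask <- matrix(FALSE, nrow(data), length(rates),
                   dimnames = list(NULL, names(rates)))
    offset <- if (mechanism == "MAR") {
      zs <- function(v) (v - mean(v)) / stats::sd(v)
      -0.6 * zs(as.numeric(data$age)) - 0.4 * zs(as.numeric(data$parent_edu))
    } else {
      rep(0, nrow(data))
    }
    for (col in names(rates)) {
      r <- rates[[col]]
      if (r == 0) next
      a <- calibrate_intercept(offset, r)
      m <- stats::rbinom(nrow(data), 1L, invlogit(a + offset)) == 1L
      mask[, col] <- m
      data[[col]][m] <- NA
    }
    attr(data, "miss_mask") <- mask
    data
  })
}

#' Split a cohort into matched discovery and validation arms
#'
#' Randomly assigns participants to two arms of (near-)equal size, stratified
#' on site and sex so that within every site-by-sex stratum the arm counts
#' differ by at most one, and overall sizes differ by at most one. This
#' emulates a pre-established reproducible matched-samples split.
#'
#' @param data Cohort data.frame with `site` and `sex` columns.
#' @param seed Integer seed.
#' @return Factor of arm labels (`discovery`/`validation`), one per row.
#' @export
split_arms <- function(data, seed = NULL) {
  stopifnot(all(c("site", "sex") %in% names(data)))
  with_seed(seed, {
    arm <- integer(nrow(data))
    strata <- interaction(data$site, data$sex, drop = TRUE)
    extra <- 0L  # running imbalance from odd strata; keep |extra| <= 1
    for (s in levels(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      k <- length(idx) %/% 2
      first <- if (length(idx) %% 2 == 1L) {
        # give the odd participant to whichever arm is behind
        if (extra <= 0L) { extra <- extra + 1L; 1L } else { extra <- extra - 1L; 2L }
      } else 1L
      n1 <- k + as.integer(length(idx) %% 2 == 1L && first == 1L)
      arm[idx[seq_len(n1)]] <- 1L
      arm[idx[-seq_len(n1)]] <- 2L
    }
    factor(ifelse(arm == 1L, "discovery", "validation"),
           levels = c("discovery", "validation"))
  })
}

#' Simulate a full ABCD-like cohort
#'
#' End-to-end generator: demographics, copula-correlated baseline and
#' concurrent impulsivity measures, a matched two-arm split, yearly initiation
#' indicators with carry-forward (calibrated to the target cumulative rate),
#' bounded perceived-harm totals, and injected missingness. The generating
#' truth (coefficients, calibrated intercept, site effects, tau targets,
#' seed) is attached as attribute `truth`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; all stages derive sub-seeds from it.
#' @return A data.frame, one row per participant, of class `cohort`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  target <- corr_target(config$tau)

  demo <- with_seed(derive_seed(seed, 1), {
    sibling <- factor(sample(c("single", "sibling", "twin"), n, replace = TRUE,
                             prob = c(0.2, 0.7, 0.1)),
                      levels = c("single", "sibling", "twin"))
    data.frame(
      pid = sprintf("P%06d", seq_len(n)),
      site = sample.int(config$n_sites, n, replace = TRUE,
                        prob = config$site_weights),
      age = round(stats::rnorm(n, 9.9, 0.6), 1),
      sex = stats::rbinom(n, 1L, 0.522),  # 1 = male
      sibling = sibling,
      income = sample.int(10L, n, replace = TRUE,
                          prob = stats::dbinom(0:9, 9, 0.6)),
      parent_edu = sample.int(5L, n, replace = TRUE,
                              prob = c(0.05, 0.15, 0.3, 0.3, 0.2)),
      par_sub = stats::rbinom(n, 1L, 0.25),
      par_mh = stats::rbinom(n, 1L, 0.30),
      par_leg = stats::rbinom(n, 1L, 0.10)
    )
  })

  # Baseline and concurrent measurement windows share the same cross-sectional
  # copula; windows are linked person-level through latent autocorrelation.
  a <- config$window_autocorr
  meas <- with_seed(derive_seed(seed, 2), {
    z_b <- draw_latent(n, target)
    z_c <- a * z_b + sqrt(1 - a^2) * draw_latent(n, target)
    xb <- latent_to_margins(z_b, config$marginals)
    xc <- latent_to_margins(z_c, config$marginals)
    names(xb) <- paste0(names(xb), "_b")
    names(xc) <- paste0(names(xc), "_c")
    cbind(xb, xc)
  })

  cohort <- cbind(demo, meas)
  cohort$arm <- split_arms(cohort, seed = derive_seed(seed, 3))

  init <- generate_initiation(cohort, config$initiation_model, cohort$site,
                              seed = derive_seed(seed, 4))
  cohort$initiation <- as.integer(init)

  # Distribute first-initiation year among initiators following the
  # cumulative year profile, then carry forward.
  yearly <- with_seed(derive_seed(seed, 5), {
    inc <- diff(c(0, config$year_profile))
    first <- sample.int(4L, sum(init == 1L), replace = TRUE, prob = inc)
    m <- matrix(0L, n, 4, dimnames = list(NULL, paste0("init_y", 0:3)))
    m[cbind(which(init == 1L), first)] <- 1L
    carry_forward_initiation(m)
  })
  cohort <- cbind(cohort, yearly)

  hseed <- derive_seed(seed, 6)
  shifts <- c(alcohol = 0, nicotine = 0.2, cannabis = 0.1)
  for (sub in names(config$harm_substances)) {
    cohort[[paste0("harm_", sub)]] <- generate_harm(
      cohort, config$harm_model, cohort$site,
      denominator = config$harm_substances[[sub]],
      shift = shifts[[sub]] %||% 0,
      seed = derive_seed(hseed, match(sub, names(config$harm_substances)))
    )
  }

  cohort <- inject_missingness(cohort, config$missingness$rates,
                               mechanism = config$missingness$mechanism,
                               seed = derive_seed(seed, 7))

  attr(cohort, "truth") <- list(
    beta = config$initiation_model$beta,
    beta0 = attr(init, "beta0"),
    site_sd = config$initiation_model$site_sd,
    u_site = attr(init, "u_site"),
    target_rate = config$initiation_model$target_rate,
    tau = target$tau,
    harm_beta = config$harm_model$beta,
    seed = seed
  )
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' Write a cohort to CSV with a JSON truth sidecar
#'
#' Emits a long-format table (one row per participant-year: time-varying
#' initiation indicator and window-matched measures) plus
#' `<stem>_truth.json` holding the generating truth, and a wide per-participant
#' CSV `<stem>_wide.csv`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param stem Output path stem (no extension).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, stem) {
  wide_path <- paste0(stem, "_wide.csv")
  long_path <- paste0(stem, ".csv")
  truth_path <- paste0(stem, "_truth.json")
  utils::write.csv(as.data.frame(cohort), wide_path, row.names = FALSE)
  long <- cohort_long(cohort)
  utils::write.csv(long, long_path, row.names = FALSE)
  truth <- attr(cohort, "truth")
  truth$u_site <- NULL
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(long = long_path, wide = wide_path, truth = truth_path))
}

#' Pivot a cohort to participant-year long format
#'
#' @param cohort Output of [simulate_cohort()].
#' @return Data.frame with one row per participant-year (years 0-3); measures
#'   take their baseline values in years 0-1 and concurrent values in years
#'   2-3.
#' @export
cohort_long <- function(cohort) {
  base_cols <- c("pid", "site", "arm", SETA_VARS)
  out <- do.call(rbind, lapply(0:3, function(yr) {
    suf <- if (yr <= 1) "_b" else "_c"
    d <- cohort[, base_cols, drop = FALSE]
    d$year <- yr
    for (v in c(SETB_MEASURES, SETC_MEASURES)) {
      d[[v]] <- cohort[[paste0(v, suf)]]
    }
    d$initiation <- cohort[[paste0("init_y", yr)]]
    d
  }))
  out[order(out$pid, out$year), , drop = FALSE]
}
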