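## Multiple imputation by chained-equations predictive mean matching, and
## Rubin's-rules pooling.

#' Multiple imputation by predictive mean matching
#'
#' Chained-equations imputation: each incomplete column is regressed on all
#' other columns (covariates and outcomes alike serve as predictors), a
#' Bayesian draw of the regression coefficients produces predictions for the
#' missing rows, and each missing cell receives the observed value of one of
#' the `k_donors` nearest observed rows in predicted-value space. Matching on
#' donors preserves the observed support exactly, so binary and ordinal
#' columns never receive impossible values. Factors are imputed on integer
#' codes (still donor-matched) and restored.
#'
#' @param data Data.frame with missing values. Columns with no missingness
#'   are used as predictors only.
#' @param m Number of completed datasets (>= 2).
#' @param k_donors Donor pool size for matching.
#' @param iterations Chained-equation sweeps per imputation.
#' @param seed Integer seed.
#' @param exclude Columns to leave out of the imputation model entirely
#'   (e.g. identifiers); they are carried through unchanged.
#' @return Object of class `imputation_set`: list with `completed` (list of m
#'   complete data.frames), `mask`, `order` (sweep order), and the call
#'   parameters.
#' @export
pmm_impute <- function(data, m = 5L, k_donors = 5L, iterations = 10L,
                       seed = NULL, exclude = c("pid", "arm")) {
  if (m < 2) stop_domain("`m` must be >= 2")
  exclude <- intersect(exclude, names(data))
  work_cols <- setdiff(names(data), exclude)
  work <- data[, work_cols, drop = FALSE]

  # numeric working copy; remember factor encodings
  fct <- list()
  for (v in work_cols) {
    if (is.factor(work[[v]]) || is.character(work[[v]])) {
      f <- factor(work[[v]])
      fct[[v]] <- levels(f)
      work[[v]] <- as.integer(f)
    } else {
      work[[v]] <- as.numeric(work[[v]])
    }
  }
  mask <- is.na(as.matrix(work))
  incomplete <- names(which(colSums(mask) > 0))
  for (v in incomplete) {
    if (sum(!mask[, v]) < k_donors) {
      stop("column ", v, " has fewer observed values than `k_donors`; ",
           "cannot impute", call. = FALSE)
    }
  }
  # sweep order: least missing first (fixed, recorded in the result)
  incomplete <- incomplete[order(colSums(mask)[incomplete])]

  completed <- with_seed(seed, {
    lapply(seq_len(m), function(im) {
      cur <- as.matrix(work)
      # initialize missing cells from observed values
      for (v in incomplete) {
        obs <- cur[!mask[, v], v]
        cur[mask[, v], v] <- sample(obs, sum(mask[, v]), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (v in incomplete) {
          cur[, v] <- pmm_one_column(cur, v, mask[, v], k_donors)
        }
      }
      out <- as.data.frame(cur)
      for (v in names(fct)) {
        out[[v]] <- factor(fct[[v]][out[[v]]], levels = fct[[v]])
      }
      if (length(exclude)) out <- cbind(data[, exclude, drop = FALSE], out)
      out[names(data)]
    })
  })
  structure(list(completed = completed, mask = mask, order = incomplete,
                 m = m, k_donors = k_donors, iterations = iterations,
                 seed = seed),
            class = "imputation_set")
}

# One PMM update of column v given current completed matrix.
# Bayesian linear regression draw (normal approximation with a small ridge
# for numerical stability), then type-1 matching: observed rows ranked by
# |yhat_obs(beta_hat) - yhat_mis(beta_star)|, a donor drawn among the k
# nearest.
pmm_one_column <- function(cur, v, miss, k_donors) {
  yobs <- cur[!miss, v]
  X <- cbind(1, cur[, setdiff(colnames(cur), v), drop = FALSE])
  Xobs <- X[!miss, , drop = FALSE]
  Xmis <- X[miss, , drop = FALSE]
  XtX <- crossprod(Xobs)
  diag(XtX) <- diag(XtX) * (1 + 1e-8) + 1e-8
  Xty <- crossprod(Xobs, yobs)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), Xty))
  resid <- yobs - drop(Xobs %*% beta_hat)
  df <- max(length(yobs) - ncol(Xobs), 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  beta_star <- beta_hat +
    backsolve(R, stats::rnorm(ncol(Xobs))) * sqrt(sigma2)
  yhat_obs <- drop(Xobs %*% beta_hat)
  yhat_mis <- drop(Xmis %*% beta_star)
  out <- cur[, v]
  mi <- which(miss)
  # donor search on sorted predictions: the k nearest observed rows lie among
  # the k neighbors on each side of the insertion point
  ord <- order(yhat_obs)
  yo <- yhat_obs[ord]
  vo <- yobs[ord]
  n_obs <- length(yo)
  pos <- findInterval(yhat_mis, yo)
  for (j in seq_along(mi)) {
    lo <- max(1L, pos[j] - k_donors)
    hi <- min(n_obs, pos[j] + k_donors)
    cand <- lo:hi
    nearest <- cand[order(abs(yo[cand] - yhat_mis[j]))[seq_len(k_donors)]]
    out[mi[j]] <- vo[nearest[sample.int(k_donors, 1)]]
  }
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` per-imputation estimates and squared standard errors into the
#' pooled point estimate `Qbar`, within-imputation variance `W`,
#' between-imputation variance `B`, total variance `T = W + (1 + 1/m) B`,
#' the large-sample Rubin degrees of freedom, and a two-sided p-value from a
#' t reference.
#'
#' @param estimates Numeric vector of m point estimates.
#' @param variances Numeric vector of m squared standard errors (> 0).
#' @return Object of class `pooled_estimate` (a list): `qbar`, `w`, `b`,
#'   `t`, `se`, `df`, `p`, `m`.
#' @export
#' @examples
#' rubin_pool(c(1, 3), c(1, 1))  # qbar 2, W 1, B 2, T 4, SE 2
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop_domain("need m >= 2 imputations (between-variance undefined)")
  if (length(variances) != m) stop_domain("lengths differ")
  if (any(variances <= 0)) stop_domain("variances must be > 0")
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  tt <- w + (1 + 1 / m) * b
  df <- if (b == 0) Inf else (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
  se <- sqrt(tt)
  p <- 2 * stats::pt(-abs(qbar / se), df = df)
  structure(list(qbar = qbar, w = w, b = b, t = tt, se = se, df = df,
                 p = p, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled over m=%d: Q = %.4g (SE %.4g), W = %.4g, B = %.4g, T = %.4g, df = %.3g, p = %.3g\n",
              x$m, x$qbar, x$se, x$w, x$b, x$t, x$df, x$p))
  invisible(x)
}

#' Fit a model on each completed dataset and pool the coefficients
#'
#' Applies `fit_fun` (returning an `impulsim_fit`) to every completed table
#' in an [pmm_impute()] result and pools each fixed-effect coefficient by
#' [rubin_pool()].
#'
#' @param imp An `imputation_set`.
#' @param fit_fun Function of one data.frame returning an `impulsim_fit`.
#' @return Data.frame with one row per coefficient: pooled estimate, SE, W,
#'   B, T, df, p.
#' @export
pool_fits <- function(imp, fit_fun) {
  stopifnot(inherits(imp, "imputation_set"))
  fits <- lapply(imp$completed, fit_fun)
  est <- sapply(fits, function(f) f$core$coefficients)
  v <- sapply(fits, function(f) f$core$se^2)
  out <- do.call(rbind, lapply(seq_len(nrow(est)), function(i) {
    pl <- rubin_pool(est[i, ], v[i, ])
    data.frame(term = rownames(est)[i], estimate = pl$qbar, se = pl$se,
               w = pl$w, b = pl$b, t = pl$t, df = pl$df, p = pl$p)
  }))
  rownames(out) <- NULL
  out
}
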