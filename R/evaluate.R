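## Out-of-sample evaluation: AUC with DeLong uncertainty, pairwise model
## comparison, PPV/recall, MSE, median-split AUC, and 10-fold CV.

#' Out-of-sample risk scores
#'
#' Predicted probabilities for new rows from a fitted model: fixed effects
#' (with the discovery-arm standardization transform re-applied) plus the
#' estimated intercept of the row's site. Sites unseen during fitting fall
#' back to the population intercept with a message.
#'
#' @param fit An `impulsim_fit`.
#' @param newdata Validation rows (schema must match the training schema).
#' @return Numeric vector of predicted probabilities (`NA` where predictors
#'   are missing).
#' @export
predict_out_of_sample <- function(fit, newdata) {
  stopifnot(inherits(fit, "impulsim_fit"))
  des <- build_design(newdata, fit$predictors, stats = fit$standardize)
  if (!identical(colnames(des$X), fit$design_names)) {
    stop_domain("validation design does not match training design")
  }
  eta <- drop(cbind(1, des$X) %*% fit$core$coefficients)
  unseen <- newdata$site < 1 | newdata$site > length(fit$core$u_site)
  if (any(unseen, na.rm = TRUE)) {
    message(sum(unseen, na.rm = TRUE),
            " rows from unseen sites scored with the population intercept")
  }
  eta <- eta + site_effect(fit, newdata$site)
  invlogit(eta)
}

#' @export
predict.impulsim_fit <- function(object, newdata, ...) {
  predict_out_of_sample(object, newdata)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive scores above a
#' random negative, counting ties as one half. Computed via midranks.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 outcomes.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_domain("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values for a score vector: V10 (one per positive) and V01
# (one per negative).
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v10 <- vapply(pos, function(s) mean((neg < s) + 0.5 * (neg == s)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong comparison of two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two models scored on the same
#' rows, using the DeLong structural components (placement values): the
#' variance of the AUC difference accounts for the correlation between the
#' two score vectors. Also returns each model's DeLong 95% CI. Comparing a
#' model with itself (or any pair with degenerate difference variance)
#' returns p = 1 by convention.
#'
#' @param scores1,scores2 Risk scores of the two models on identical rows.
#' @param labels Binary outcomes.
#' @param conf_level Confidence level for the per-model intervals.
#' @return List: `auc1`, `auc2`, `delta`, `se`, `p`, `ci1`, `ci2`.
#' @export
delong_compare <- function(scores1, scores2, labels, conf_level = 0.95) {
  ok <- stats::complete.cases(scores1, scores2, labels)
  scores1 <- scores1[ok]; scores2 <- scores2[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2) {
    stop_domain("both outcome classes must be present")
  }
  p1 <- delong_placements(scores1, labels)
  p2 <- delong_placements(scores2, labels)
  m <- length(p1$v10); n <- length(p1$v01)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- p1$auc - p2$auc
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- function(pl, k) {
    se <- sqrt(stats::var(pl$v10) / m + stats::var(pl$v01) / n)
    c(pl$auc - zq * se, pl$auc + zq * se)
  }
  if (var_delta <= .Machine$double.eps) {
    p <- 1
    se <- 0
  } else {
    se <- sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(delta) / se)
  }
  list(auc1 = p1$auc, auc2 = p2$auc, delta = delta, se = se, p = p,
       ci1 = ci(p1), ci2 = ci(p2))
}

#' DeLong confidence interval for a single AUC
#'
#' @inheritParams delong_compare
#' @param scores Risk scores.
#' @return List: `auc`, `se`, `ci`.
#' @export
delong_ci <- function(scores, labels, conf_level = 0.95) {
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  pl <- delong_placements(scores, labels)
  m <- length(pl$v10); n <- length(pl$v01)
  se <- sqrt(stats::var(pl$v10) / m + stats::var(pl$v01) / n)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = pl$auc, se = se, ci = c(pl$auc - zq * se, pl$auc + zq * se))
}

#' Positive predictive value and recall of a thresholded classifier
#'
#' PPV = TP/(TP+FP), recall = TP/(TP+FN). The threshold rule is either a
#' fixed probability cut (default 0.5) or "top-k": flag the
#' highest-scoring fraction of rows (e.g. the outcome prevalence). With zero
#' predicted positives PPV is undefined and returned as `NA` with a warning.
#'
#' @param scores Risk scores.
#' @param labels Binary outcomes.
#' @param rule List: `type = "prob"` with `value`, or `type = "topk"` with
#'   `prop` (fraction flagged).
#' @return List with `ppv`, `recall`, `n_flagged`, and the rule used.
#' @export
ppv_recall <- function(scores, labels, rule = list(type = "prob", value = 0.5)) {
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% 0:1)) stop_domain("labels must be binary 0/1")
  flagged <- switch(rule$type,
    prob = scores >= rule$value,
    topk = {
      k <- max(1L, round(rule$prop * length(scores)))
      scores >= sort(scores, decreasing = TRUE)[k]
    },
    stop_domain("unknown threshold rule type: ", rule$type)
  )
  tp <- sum(flagged & labels == 1)
  fp <- sum(flagged & labels == 0)
  fn <- sum(!flagged & labels == 1)
  ppv <- if (tp + fp == 0) {
    warning("no predicted positives; PPV undefined", call. = FALSE)
    NA_real_
  } else tp / (tp + fp)
  list(ppv = ppv, recall = tp / (tp + fn), n_flagged = sum(flagged),
       rule = rule)
}

#' Median-split AUC for a bounded total score
#'
#' Dichotomizes the observed totals at their median (values equal to the
#' median go to the low class; the convention is recorded in the result) and
#' computes the AUC of the continuous predictions against the dichotomized
#' observations.
#'
#' @param predicted Continuous predicted totals.
#' @param observed Observed totals.
#' @return List: `auc`, `median`, `tie_convention`.
#' @export
median_split_auc <- function(predicted, observed) {
  ok <- stats::complete.cases(predicted, observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  med <- stats::median(observed)
  cls <- as.integer(observed > med)  # ties at the median -> low class
  if (length(unique(cls)) < 2) {
    stop_domain("median split degenerate: observed totals effectively constant")
  }
  list(auc = auc(predicted, cls), median = med,
       tie_convention = "ties at median assigned to low class")
}

#' Stratified k-fold cross-validated scores
#'
#' Splits rows into `k` folds stratified on the binary outcome, fits the
#' model on each training complement, and scores the held-out fold, so every
#' row is scored exactly once. The concatenated out-of-fold scores feed the
#' same AUC machinery as split-half validation.
#'
#' @param data Cohort rows.
#' @param fit_fun Function `(training_rows) -> impulsim_fit`.
#' @param outcome Outcome column used for stratification and evaluation.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed fixing the folds.
#' @return List: `scores` (aligned with `data` rows), `fold` assignment.
#' @export
kfold_cv <- function(data, fit_fun, outcome = "initiation", k = 10L,
                     seed = NULL) {
  if (k < 2 || k > nrow(data)) stop_domain("`k` must be in [2, nrow(data)]")
  y <- data[[outcome]]
  fold <- if (k == nrow(data)) {
    seq_len(k)  # leave-one-out
  } else {
    with_seed(seed, {
      f <- integer(nrow(data))
      for (cls in unique(y[!is.na(y)])) {
        idx <- which(!is.na(y) & y == cls)
        f[idx] <- sample(rep_len(sample.int(k), length(idx)))
      }
      if (anyNA(y)) {
        f[is.na(y)] <- sample(rep_len(sample.int(k), sum(is.na(y))))
      }
      f
    })
  }
  if (k < nrow(data) && all(y %in% 0:1, na.rm = TRUE)) {
    per_fold_pos <- vapply(seq_len(k), function(f) {
      sum(y[fold == f] == 1, na.rm = TRUE)
    }, numeric(1))
    if (any(per_fold_pos == 0)) {
      stop("stratification failed: some folds contain no positive cases",
           call. = FALSE)
    }
  }
  scores <- rep(NA_real_, nrow(data))
  for (f in seq_len(k)) {
    fit <- fit_fun(data[fold != f, , drop = FALSE])
    scores[fold == f] <- predict_out_of_sample(fit, data[fold == f, , drop = FALSE])
  }
  list(scores = scores, fold = fold)
}

#' Out-of-sample comparison of the nested predictor-set models
#'
#' Fits the reduced demographics-only model (Set A) and the three richer
#' models (A+B questionnaire, A+C behavioral, A+B+C full) on the discovery
#' arm, scores the validation arm, and reports each model's AUC with DeLong
#' 95% CI, the pairwise DeLong p against the Set-A reduced model, and
#' PPV/recall (initiation) or MSE and median-split AUC (harm totals).
#'
#' @param discovery,validation Cohort rows for the two arms.
#' @param outcome_kind `"initiation"` or `"harm"`.
#' @param outcome Outcome column.
#' @param window Measurement window for sets B/C.
#' @param denominator Harm-model denominator (ignored for initiation).
#' @param penalty_scale Passed to the fitting functions.
#' @param threshold_rule Passed to [ppv_recall()].
#' @return Data.frame of class `model_comparison`, one row per model.
#' @export
compare_predictor_sets <- function(discovery, validation,
                                   outcome_kind = c("initiation", "harm"),
                                   outcome = NULL, window = "baseline",
                                   denominator = 9, penalty_scale = 2.5,
                                   threshold_rule = list(type = "prob", value = 0.5)) {
  outcome_kind <- match.arg(outcome_kind)
  outcome <- outcome %||%
    if (outcome_kind == "initiation") "initiation" else "harm_alcohol"
  specs <- list(A = "A", `A+B` = c("A", "B"), `A+C` = c("A", "C"),
                `A+B+C` = c("A", "B", "C"))
  fits <- lapply(specs, function(sets) {
    if (outcome_kind == "initiation") {
      fit_initiation_model(discovery, sets = sets, window = window,
                           outcome = outcome, penalty_scale = penalty_scale)
    } else {
      fit_harm_model(discovery, sets = sets, window = window,
                     outcome = outcome, denominator = denominator,
                     penalty_scale = penalty_scale)
    }
  })
  scores <- lapply(fits, predict_out_of_sample, newdata = validation)
  yv <- validation[[outcome]]
  ok <- Reduce(`&`, lapply(scores, function(s) !is.na(s))) & !is.na(yv)

  if (outcome_kind == "initiation") {
    labels <- yv[ok]
  } else {
    med <- stats::median(yv[ok])
    labels <- as.integer(yv[ok] > med)
  }
  rows <- lapply(names(specs), function(nm) {
    s <- scores[[nm]][ok]
    ci <- delong_ci(s, labels)
    cmp <- if (nm == "A") list(p = NA_real_) else
      delong_compare(s, scores[["A"]][ok], labels)
    row <- data.frame(model = nm, auc = ci$auc, ci_lo = ci$ci[1],
                      ci_hi = ci$ci[2], delong_p_vs_A = cmp$p)
    if (outcome_kind == "initiation") {
      pr <- ppv_recall(s, yv[ok], rule = threshold_rule)
      row$ppv <- pr$ppv; row$recall <- pr$recall; row$mse <- NA_real_
    } else {
      pred_total <- s * denominator
      row$ppv <- NA_real_; row$recall <- NA_real_
      row$mse <- mean((pred_total - yv[ok])^2)
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "n_eval") <- sum(ok)
  class(out) <- c("model_comparison", "data.frame")
  out
}
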