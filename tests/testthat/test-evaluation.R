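test_that("AUC equals the exhaustive pair-counting oracle", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  y <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auc(s, y), auc_oracle(s, y))
  # ties
  s2 <- c(0.5, 0.5, 0.5, 0.2, 0.8, 0.2)
  expect_equal(auc(s2, y), auc_oracle(s2, y))
  with_seed_test(6, {
    for (rep in 1:10) {
      sc <- sample(seq(0, 1, 0.1), 30, TRUE)
      lb <- rbinom(30, 1, 0.4)
      if (length(unique(lb)) < 2) next
      expect_equal(auc(sc, lb), auc_oracle(sc, lb))
    }
  })
  # perfect separation and chance
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  big <- with_seed_test(7, list(s = runif(20000), y = rbinom(20000, 1, 0.3)))
  expect_equal(auc(big$s, big$y), 0.5, tolerance = 0.02)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  with_seed_test(8, {
    s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
    base <- auc(s, y)
    expect_equal(auc(exp(s), y), base)
    expect_equal(auc(qlogis(plogis(s)), y), base, tolerance = 1e-12)
    expect_equal(auc(rank(s, ties.method = "average"), y), base)
  })
})

test_that("DeLong: self-comparison is null, variance matches the bootstrap", {
  d <- with_seed_test(9, {
    s1 <- rnorm(60); y <- rbinom(60, 1, plogis(1.5 * s1 - 0.5))
    while (sum(y) < 10 || sum(y) > 50) y <- rbinom(60, 1, plogis(1.5 * s1 - 0.5))
    list(s1 = s1, s2 = 0.6 * s1 + rnorm(60), y = y)
  })
  self <- delong_compare(d$s1, d$s1, d$y)
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)

  cmp <- delong_compare(d$s1, d$s2, d$y)
  boot <- with_seed_test(10, {
    vapply(1:2000, function(i) {
      idx <- sample.int(60, replace = TRUE)
      while (length(unique(d$y[idx])) < 2) idx <- sample.int(60, replace = TRUE)
      auc(d$s1[idx], d$y[idx]) - auc(d$s2[idx], d$y[idx])
    }, numeric(1))
  })
  expect_equal(cmp$se^2, var(boot), tolerance = 0.15)
  # per-model CI contains the point estimate
  expect_true(cmp$ci1[1] <= cmp$auc1 && cmp$auc1 <= cmp$ci1[2])
})

test_that("DeLong single-model machinery agrees with pROC", {
  d <- with_seed_test(11, {
    s <- rnorm(300); y <- rbinom(300, 1, plogis(s - 1))
    list(s = s, y = y)
  })
  mine <- delong_ci(d$s, d$y)
  ref <- pROC::ci.auc(pROC::roc(d$y, d$s, quiet = TRUE), method = "delong")
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(mine$ci[1], as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(mine$ci[2], as.numeric(ref[3]), tolerance = 1e-6)

  d2 <- with_seed_test(12, {
    s1 <- rnorm(200); s2 <- 0.5 * s1 + rnorm(200)
    y <- rbinom(200, 1, plogis(s1))
    list(s1 = s1, s2 = s2, y = y)
  })
  mine2 <- delong_compare(d2$s1, d2$s2, d2$y)
  ref2 <- pROC::roc.test(pROC::roc(d2$y, d2$s1, quiet = TRUE),
                         pROC::roc(d2$y, d2$s2, quiet = TRUE),
                         method = "delong", paired = TRUE)
  expect_equal(mine2$p, ref2$p.value, tolerance = 1e-8)
})

test_that("DeLong comparison of equally predictive models rejects at alpha", {
  # exchangeable null: two correlated score vectors with identical true AUC
  rej <- with_seed_test(13, {
    vapply(1:1000, function(i) {
      n <- 200
      x1 <- rnorm(n); x2 <- rnorm(n)
      y <- rbinom(n, 1, plogis(0.8 * x1 + 0.8 * x2 - 1))
      if (sum(y) < 5 || sum(y) > n - 5) return(NA)
      delong_compare(x1, x2, y)$p < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej, na.rm = TRUE) - 0.05), 0.025)
})

test_that("PPV and recall follow the confusion-table arithmetic", {
  # constructed confusion table: TP=2, FP=8, FN=3
  scores <- c(rep(0.9, 10), rep(0.1, 10))
  labels <- c(rep(1, 2), rep(0, 8), rep(1, 3), rep(0, 7))
  pr <- ppv_recall(scores, labels)
  expect_equal(pr$ppv, 0.2)
  expect_equal(pr$recall, 0.4)
  # all flagged: recall 1, PPV = prevalence
  pr2 <- ppv_recall(rep(0.8, 20), labels)
  expect_equal(pr2$recall, 1)
  expect_equal(pr2$ppv, mean(labels))
  # threshold above max score: PPV undefined with warning
  expect_warning(pr3 <- ppv_recall(scores / 10, labels), "undefined")
  expect_true(is.na(pr3$ppv))
  expect_equal(pr3$recall, 0)
  # top-k rule flags the requested fraction
  pr4 <- ppv_recall(seq(0, 1, length.out = 100), rbinom(100, 1, 0.5),
                    rule = list(type = "topk", prop = 0.1))
  expect_equal(pr4$n_flagged, 10)
})

test_that("median split dichotomizes with ties to the low class", {
  ms <- median_split_auc(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ms$auc, 1)
  # ties at the median: (1,2,2,3) -> median 2 -> classes (0,0,0,1)
  ms2 <- median_split_auc(c(10, 20, 30, 40), c(1, 2, 2, 3))
  expect_equal(ms2$median, 2)
  expect_equal(ms2$auc, 1)  # top prediction is the only high-class row
  # the opposite convention would call two rows high: documented difference
  cls_low <- as.integer(c(1, 2, 2, 3) > 2)
  cls_high <- as.integer(c(1, 2, 2, 3) >= 2)
  expect_false(identical(cls_low, cls_high))
  expect_error(median_split_auc(1:4, rep(2, 4)), "constant")
})

test_that("k-fold CV scores every row once; LOO matches the direct oracle", {
  d <- complete_cohort()[1:600, ]
  d$y20 <- with_seed_test(14, rbinom(600, 1, plogis(scale(d$cbcl_ext_b) - 1)))
  cv <- kfold_cv(d, function(tr) {
    fit_initiation_model(tr, sets = "A", outcome = "y20")
  }, outcome = "y20", k = 5, seed = 15)
  expect_false(anyNA(cv$scores))
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_identical(cv, kfold_cv(d, function(tr) {
    fit_initiation_model(tr, sets = "A", outcome = "y20")
  }, outcome = "y20", k = 5, seed = 15))

  # leave-one-out on a 20-row toy equals per-row refits
  toy <- d[1:20, ]
  toy$ybal <- rep(0:1, 10)
  ffun <- function(tr) fit_initiation_model(tr, sets = "A", outcome = "ybal",
                                            site_sd = 0.01)
  loo <- suppressMessages(kfold_cv(toy, ffun, outcome = "ybal", k = 20, seed = 16))
  direct <- vapply(seq_len(20), function(i) {
    suppressMessages(
      predict_out_of_sample(ffun(toy[-i, ]), toy[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(loo$scores, direct, tolerance = 1e-8)
})

test_that("out-of-sample scores reproduce the in-sample linear predictor", {
  d <- complete_cohort()[1:2000, ]
  fit <- fit_initiation_model(d, sets = c("A", "B"))
  s <- predict_out_of_sample(fit, d)
  des <- build_design(d, fit$predictors, stats = fit$standardize)
  eta <- drop(cbind(1, des$X) %*% fit$core$coefficients) +
    fit$core$u_site[d$site]
  expect_equal(s, plogis(eta), ignore_attr = TRUE)
  # monotone single-predictor model: scores monotone in the predictor
  # (single shared site, so no site effects break the ordering)
  d1 <- d; d1$site <- 1L
  f1 <- impulsim:::fit_model_internal(
    d1, "cbcl_ext_b", d1$initiation, trials = 1, sets = NULL,
    window = "baseline", outcome = "initiation",
    outcome_kind = "initiation", penalty_scale = 2.5, standardize = NULL,
    site_sd = 0.01)
  s1 <- predict_out_of_sample(f1, d1)
  ord <- order(d1$cbcl_ext_b)
  expect_true(all(diff(s1[ord]) >= -1e-12))
  # unseen site falls back to the population intercept
  d2 <- d[1:5, ]; d2$site <- 99L
  expect_message(s99 <- predict_out_of_sample(fit, d2), "unseen")
})

test_that("LOO oracle check for kfold stratification failure", {
  d <- complete_cohort()[1:100, ]
  d$yrare <- c(1, rep(0, 99))
  expect_error(kfold_cv(d, identity, outcome = "yrare", k = 5, seed = 1),
               "stratification")
})
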