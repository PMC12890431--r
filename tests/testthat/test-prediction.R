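test_that("the penalty keeps estimates finite under perfect separation", {
  d <- with_seed_test(1, {
    x <- c(rnorm(20, -2), rnorm(20, 2))
    data.frame(y = rep(0:1, each = 20), cbcl_ext_b = x,
               site = rep(1:2, 20))
  })
  fit <- fit_penalized_glmm(d$y, cbind(cbcl_ext_b = scale(d$cbcl_ext_b)[, 1]),
                            d$site, penalty_scale = 2.5)
  b <- fit$coefficients[["cbcl_ext_b"]]
  expect_true(is.finite(b))
  # a normal(0, 2.5) penalty keeps even a perfect predictor within a few
  # prior SDs
  expect_lt(abs(b), 3 * 2.5)
  expect_true(all(is.finite(fit$se)))
})

test_that("penalty monotonicity: strong shrinkage kills coefficients, weak
           shrinkage approaches the unpenalized ML fit", {
  d <- with_seed_test(2, {
    n <- 3000
    x1 <- rnorm(n); x2 <- rnorm(n)
    eta <- -1 + 0.8 * x1 - 0.4 * x2
    data.frame(y = rbinom(n, 1, plogis(eta)), x1 = x1, x2 = x2,
               site = sample(1:3, n, TRUE))
  })
  X <- cbind(x1 = d$x1, x2 = d$x2)
  scales <- c(0.001, 0.1, 1, 100)
  b1 <- vapply(scales, function(s) {
    fit_penalized_glmm(d$y, X, d$site, penalty_scale = s,
                       site_sd = 0.01)$coefficients[["x1"]]
  }, numeric(1))
  expect_true(all(diff(abs(b1)) > 0))  # |beta| grows as the penalty relaxes
  expect_lt(abs(b1[1]), 0.01)
  ml <- glm(y ~ x1 + x2, family = binomial(), data = d)
  expect_equal(b1[4], coef(ml)[["x1"]], tolerance = 0.02)
})

test_that("weak-penalty multilevel fit agrees with Laplace ML (glmmTMB)", {
  d <- with_seed_test(5, {
    n <- 4000
    site <- sample(1:15, n, TRUE)
    u <- rnorm(15, 0, 0.4)
    x <- rnorm(n)
    data.frame(y = rbinom(n, 1, plogis(-1.5 + 0.5 * x + u[site])),
               x = x, site = site)
  })
  fit <- fit_penalized_glmm(d$y, cbind(x = d$x), d$site, penalty_scale = 100)
  tmb <- glmmTMB::glmmTMB(y ~ x + (1 | site), family = binomial(), data = d)
  expect_equal(fit$coefficients[["x"]], glmmTMB::fixef(tmb)$cond[["x"]],
               tolerance = 0.02)
  tmb_sd <- sqrt(glmmTMB::VarCorr(tmb)$cond$site[1, 1])
  expect_equal(fit$site_sd, tmb_sd, tolerance = 0.25)
})

test_that("the full pipeline model recovers a configured odds ratio", {
  # moderate scale here; the headline 50k recovery runs in the acceptance suite
  big <- complete_cohort()
  fit <- fit_initiation_model(big)
  truth <- attr(big, "truth")
  expect_true(fit$core$converged)
  est <- exp(coef(fit)[["upps_per_b"]])
  se <- fit$core$se[["upps_per_b"]]
  expect_lt(abs(log(est) - truth$beta[["upps_per_b"]]), 3.3 * se)
  # site-intercept SD recovered within simulation tolerance
  expect_equal(fit$core$site_sd, truth$site_sd, tolerance = 0.5)
})

test_that("harm model: bounds enforced, coefficients recovered, predictions bounded", {
  big <- complete_cohort()
  fit <- fit_harm_model(big, outcome = "harm_alcohol", denominator = 9)
  truth <- attr(big, "truth")
  b <- coef(fit)[["upps_ss_c"]]
  expect_lt(abs(b - truth$harm_beta[["upps_ss_c"]]),
            4 * fit$core$se[["upps_ss_c"]])
  mu <- predict_out_of_sample(fit, big[1:500, ])
  expect_true(all(mu * 9 >= 0 & mu * 9 <= 9))
  bad <- big[1:50, ]; bad$harm_alcohol[1] <- 12
  expect_error(fit_harm_model(bad, outcome = "harm_alcohol", denominator = 9),
               "\\[0, 9\\]")
})

test_that("all-zero harm scores give a finite near-zero fitted mean", {
  d <- with_seed_test(3, data.frame(age = rnorm(80, 10, 0.5),
                                    site = sample(1:3, 80, TRUE),
                                    harm = 0L))
  fit <- impulsim:::fit_model_internal(
    d, "age", d$harm, trials = 9, sets = "A", window = "concurrent",
    outcome = "harm", outcome_kind = "harm", penalty_scale = 2.5,
    standardize = NULL, site_sd = NULL)
  expect_true(all(is.finite(fit$core$coefficients)))
  mu <- predict_out_of_sample(fit, d)
  expect_lt(max(mu), 0.05)
})

test_that("effect sizes: odds-ratio and percent-total round trips", {
  big <- complete_cohort()
  fit <- fit_initiation_model(big, sets = c("A", "B"))
  eff <- effect_sizes(fit, arm = "discovery")
  expect_equal(eff$estimate[eff$predictor == "cbcl_ext_b"],
               exp(coef(fit)[["cbcl_ext_b"]]))
  expect_true(all(eff$estimate > 0))
  expect_true(all(eff$lo <= eff$estimate & eff$estimate <= eff$hi))
  expect_true(all(eff$p_adj >= eff$p - 1e-15))

  # beta = 0 -> OR 1; beta = ln(1.21) -> OR 1.21 (construct directly)
  fit0 <- fit
  fit0$core$coefficients[] <- 0
  fit0$core$coefficients[["cbcl_ext_b"]] <- log(1.21)
  eff0 <- effect_sizes(fit0)
  expect_equal(eff0$estimate[eff0$predictor == "cbcl_ext_b"], 1.21)
  expect_equal(eff0$estimate[eff0$predictor == "age"], 1)
})

test_that("harm average marginal effect matches a finite-difference oracle", {
  big <- complete_cohort()[1:1500, ]
  fit <- fit_harm_model(big, sets = "A", outcome = "harm_alcohol")
  eff <- effect_sizes(fit, data = big)
  # oracle: numerical derivative of the mean response in percent-of-total
  des <- build_design(big, fit$predictors, stats = fit$standardize)
  eta <- drop(cbind(1, des$X) %*% fit$core$coefficients) +
    impulsim:::site_effect(fit, big$site)
  for (v in c("age", "income")) {
    bj <- fit$core$coefficients[[v]]
    oracle <- 100 * mean(plogis(eta + bj) - plogis(eta))
    expect_equal(eff$estimate[eff$predictor == v], oracle, tolerance = 1e-6)
  }
})

test_that("replication flags reproduce the three logical outcomes", {
  disc <- data.frame(predictor = c("a", "b", "c"),
                     estimate = c(1.2, 1.2, 1.2), lo = 1, hi = 1.5,
                     p = 0.001, p_adj = c(0.01, 0.01, 0.01))
  val <- data.frame(predictor = c("a", "b", "c"),
                    estimate = c(1.15, 0.9, 1.2), lo = 0.8, hi = 1.5,
                    p = 0.01, p_adj = c(0.03, 0.01, 0.08))
  out <- replication_flags(disc, val, null_value = 1)
  expect_identical(out$replicated, c(TRUE, FALSE, FALSE))
  # order-insensitive on the validation side
  out2 <- replication_flags(disc, val[c(3, 1, 2), ], null_value = 1)
  expect_identical(out2$replicated, out$replicated)
  expect_error(replication_flags(disc, val[1:2, ]), "different predictors")
})

test_that("Wald intervals on null data cover OR = 1 at the nominal rate", {
  cover <- with_seed_test(31, {
    vapply(1:300, function(i) {
      n <- 800
      x <- rnorm(n)
      d <- data.frame(y = rbinom(n, 1, 0.15), x = x,
                      site = sample(1:5, n, TRUE))
      fit <- fit_penalized_glmm(d$y, cbind(x = d$x), d$site, site_sd = 0.01)
      b <- fit$coefficients[["x"]]; se <- fit$se[["x"]]
      abs(b) < qnorm(0.975) * se
    }, logical(1))
  })
  expect_equal(mean(cover), 0.95, tolerance = 0.035)
})
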