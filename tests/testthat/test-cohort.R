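test_that("covariate generation hits Kendall-tau targets and marginal shapes", {
  cfg <- cohort_config()
  x <- generate_covariates(10000, cfg$tau, cfg$marginals, seed = 11)
  # the strongest cross-questionnaire pair: BAS fun-seeking x UPPS
  # sensation-seeking, target 0.22
  expect_equal(cor(x$bas_fs, x$upps_ss, method = "kendall"), 0.22,
               tolerance = 0.1)  # tolerance on ratio; absolute check below
  expect_lt(abs(cor(x$bas_fs, x$upps_ss, method = "kendall") - 0.22), 0.02)
  # behavioral vs questionnaire stays tiny
  expect_lt(abs(cor(x$ssrt, x$cbcl_ext, method = "kendall")), 0.08)
  # right-skewed marginals have positive sample skewness
  for (v in c("upps_nu", "cbcl_ext", "bas_dr", "ssrt")) {
    expect_gt(impulsim:::sample_skewness(x[[v]]), 0)
  }
  # support: ssrt shifted gamma stays above its shift
  expect_true(all(x$ssrt > 120))
})

test_that("an identity correlation target yields near-independent columns", {
  cfg <- cohort_config()
  vars <- c("upps_nu", "bas_dr", "ssrt")
  tgt <- diag(3)
  dimnames(tgt) <- list(vars, vars)
  x <- generate_covariates(10000, tgt, cfg$marginals[vars], seed = 3)
  taus <- cor(as.matrix(x), method = "kendall")
  expect_true(all(abs(taus[upper.tri(taus)]) <= 0.03))
})

test_that("copula round trip holds across the target range", {
  cfg <- cohort_config()
  for (tgt in c(-0.5, -0.2, 0.1, 0.38, 0.5)) {
    m <- matrix(c(1, tgt, tgt, 1), 2,
                dimnames = list(c("upps_nu", "cbcl_ext"),
                                c("upps_nu", "cbcl_ext")))
    x <- generate_covariates(50000, m, cfg$marginals, seed = 7)
    expect_lt(abs(cor(x$upps_nu, x$cbcl_ext, method = "kendall") - tgt), 0.02)
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n = 400)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(a$cbcl_ext_b, c$cbcl_ext_b))
})

test_that("intercept calibration matches closed forms and generic targets", {
  expect_equal(calibrate_intercept(rep(0, 50), 0.5), 0, tolerance = 1e-6)
  expect_equal(calibrate_intercept(rep(0, 50), 0.033), log(0.033 / 0.967),
               tolerance = 1e-6)
  # random offsets: achieved mean risk equals the target
  offset <- with_seed_test(2, rnorm(5000, 0, 1.3))
  b0 <- calibrate_intercept(offset, 0.1)
  expect_equal(mean(plogis(b0 + offset)), 0.1, tolerance = 1e-7)
  expect_error(calibrate_intercept(numeric(0), 0.5), "non-empty")
  expect_error(calibrate_intercept(0, 1.2), "in \\(0, 1\\)")
})

test_that("initiation simulation hits target rates", {
  ch <- small_cohort()
  m0 <- generating_model(beta = c(age = 0), target_rate = 0.5)
  y <- generate_initiation(ch, m0, ch$site, seed = 8)
  expect_equal(mean(y), 0.5, tolerance = 3 * sqrt(0.25 / nrow(ch)) / 0.5)
  m1 <- generating_model(beta = c(age = 0.3, cbcl_ext_b = 0.19),
                         site_sd = 0.3, target_rate = 0.033)
  big <- complete_cohort()
  y1 <- generate_initiation(big, m1, big$site, seed = 9)
  expect_lt(abs(mean(y1) - 0.033), 3 * sqrt(0.033 * 0.967 / nrow(big)))
})

test_that("site effects have the configured between-site spread", {
  big <- complete_cohort()
  m <- generating_model(beta = c(age = 0), site_sd = 0.5, target_rate = 0.3)
  sds <- vapply(1:20, function(s) {
    y <- generate_initiation(big, m, big$site, seed = 100 + s)
    sd(attr(y, "u_site"))
  }, numeric(1))
  expect_equal(mean(sds), 0.5, tolerance = 0.1)
})

test_that("harm totals respect bounds and the binomial mean", {
  ch <- small_cohort()
  m <- generating_model(beta = c(age = 0), beta0 = 0)
  h9 <- generate_harm(ch, m, ch$site, denominator = 9, seed = 4)
  expect_true(all(h9 >= 0 & h9 <= 9))
  expect_equal(mean(h9), 4.5, tolerance = 0.1)
  h15 <- generate_harm(ch, m, ch$site, denominator = 15, seed = 4)
  expect_true(all(h15 >= 0 & h15 <= 15))
  mlow <- generating_model(beta = c(age = 0), beta0 = -30)
  expect_true(all(generate_harm(ch, mlow, ch$site, 9, seed = 1) == 0))
  expect_error(generate_harm(ch, m, ch$site, denominator = 7), "9 or 15")
})

test_that("carry-forward initiation is cumulative and ignores missing", {
  expect_equal(carry_forward_initiation(c(0, 0, 1, 0)), c(0, 0, 1, 1))
  expect_equal(carry_forward_initiation(c(0, 0, 0, 0)), c(0, 0, 0, 0))
  expect_equal(carry_forward_initiation(c(1, NA, 0, 0)), c(1, 1, 1, 1))
  expect_equal(carry_forward_initiation(c(NA, 0, 1, NA)), c(NA, 0, 1, 1))
  m <- rbind(c(0, 1, 0, 0), c(0, 0, 0, 1))
  out <- carry_forward_initiation(m)
  expect_true(all(apply(out, 1, function(r) !is.unsorted(r))))
  ch <- small_cohort()
  ys <- as.matrix(ch[, paste0("init_y", 0:3)])
  expect_true(all(ys[, 4] == ch$initiation | is.na(ch$initiation)))
  expect_true(all(apply(ys, 1, function(r) !is.unsorted(r))))
})

test_that("missingness injection matches rates; MAR depends on age, MCAR does not", {
  cfg <- cohort_config(n = 10000)
  cfg$missingness$rates[] <- 0
  ch <- simulate_cohort(cfg, seed = 31)
  rates <- c(cbcl_ext_b = 0.1, ssrt_b = 0.2)

  for (mech in c("MCAR", "MAR")) {
    d <- inject_missingness(ch, rates, mechanism = mech, seed = 17)
    frac <- colMeans(is.na(d[, names(rates)]))
    expect_equal(unname(frac), unname(rates), tolerance = 0.1)
    expect_true(all(abs(frac - rates) < 0.01 + 3 * sqrt(rates / nrow(d))))
    mask <- attr(d, "miss_mask")
    # logistic check of mask-vs-age association
    pv <- summary(glm(mask[, "cbcl_ext_b"] ~ ch$age,
                      family = binomial()))$coefficients[2, 4]
    if (mech == "MAR") expect_lt(pv, 1e-6) else expect_gt(pv, 0.01)
  }
  d0 <- inject_missingness(ch, c(cbcl_ext_b = 0), seed = 1)
  expect_false(any(attr(d0, "miss_mask")))
  expect_error(inject_missingness(ch, c(age = 0.1), mechanism = "MAR"),
               "conditioning")
  expect_error(inject_missingness(ch, c(cbcl_ext_b = 1)), "rates")
})

test_that("arm split is balanced within site-by-sex strata and reproducible", {
  ch <- small_cohort()
  arm <- split_arms(ch, seed = 12)
  expect_lte(abs(sum(arm == "discovery") - sum(arm == "validation")), 1)
  tab <- table(ch$site, ch$sex, arm)
  expect_true(all(abs(tab[, , 1] - tab[, , 2]) <= 1))
  # every site present in both arms
  expect_true(all(table(ch$site, arm) > 0))
  expect_identical(arm, split_arms(ch, seed = 12))
})
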