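test_that("Spiegelhalter's z matches hand arithmetic and its null law", {
  res <- spiegelhalter_z(c(0.8, 0.4, 0.9), c(1, 0, 1))
  # hand arithmetic: -0.28 / sqrt(0.1248)
  expect_equal(res$statistic, -0.28 / sqrt(0.1248), tolerance = 1e-12)
  expect_equal(res$statistic, -0.7925939, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pnorm(-abs(res$statistic)))
  expect_error(spiegelhalter_z(rep(0.5, 4), c(1, 0, 1, 0)), "degenerate")
  # under the null the statistic is approximately standard normal
  withr::with_seed(5, {
    z <- replicate(500, {
      p <- runif(73, 0.05, 0.95)
      spiegelhalter_z(p, rbinom(73, 1, p))$statistic
    })
    expect_equal(mean(z), 0, tolerance = 0.15)
    expect_equal(sd(z), 1, tolerance = 0.12)
  })
})

test_that("score-based calibration tests return four usable results", {
  withr::with_seed(7, {
    v <- runif(73, 0.02, 0.3)
    m <- rnorm(73, 0, 0.3)
    y <- rnorm(73, m, sqrt(v))
    res <- score_calibration_tests(y, m, v)
    expect_equal(res$test, c("ls_z", "crps_z", "ls_reg", "crps_reg"))
    expect_true(all(res$applicable))
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    # constant predictive variances leave the regression tests undefined
    resc <- score_calibration_tests(y, m, rep(0.1, 73))
    expect_false(any(resc$applicable[3:4]))
    expect_true(all(resc$applicable[1:2]))
    expect_error(score_calibration_tests(1, 0, 1), "at least 3")
  })
})

test_that("score-based tests detect overdispersed forecasts", {
  withr::with_seed(8, {
    med_p <- sapply(1:100, function(i) {
      v <- runif(73, 0.02, 0.3)
      m <- rnorm(73, 0, 0.3)
      y <- rnorm(73, m, sqrt(4 * v))  # true spread twice the stated one
      score_calibration_tests(y, m, v)$p_value
    })
    expect_true(all(apply(med_p, 1, median) < 0.05))
  })
})

test_that("harmonic mean p-value stays within the input range", {
  expect_equal(harmonic_mean_p(rep(0.2, 4)), 0.2)
  expect_equal(harmonic_mean_p(c(0.01, 0.1, 0.1, 0.1)), 4 / 130)
  expect_error(harmonic_mean_p(c(0, 0.5)), "\\(0, 1\\]")
  withr::with_seed(9, {
    for (i in 1:20) {
      p <- runif(4, 0.001, 1)
      hm <- harmonic_mean_p(p)
      expect_gte(hm, min(p))
      expect_lte(hm, max(p))
      expect_equal(harmonic_mean_p(rev(p)), hm)
    }
  })
})

test_that("PIT is the predictive CDF at the observation", {
  expect_equal(pit(0.5, 0.5, 2), 0.5)
  expect_equal(pit(qnorm(0.975) * 2 + 1, 1, 4), 0.975, tolerance = 1e-9)
  withr::with_seed(10, {
    v <- runif(2000, 0.1, 2)
    m <- rnorm(2000)
    y <- rnorm(2000, m, sqrt(v))
    expect_gt(ks_uniform(pit(y, m, v))$p_value, 1e-4)
  })
})

test_that("KS uniformity test has exact small-sample behaviour", {
  expect_equal(ks_uniform(0.5)$statistic, 0.5)
  expect_lt(ks_uniform(runif(30, 0, 0.2))$p_value, 0.001)
  expect_error(ks_uniform(c(0.5, 1.3)), "\\[0, 1\\]")
  withr::with_seed(12, {
    rej <- mean(replicate(400, ks_uniform(runif(73))$p_value < 0.05))
    expect_gt(rej, 0.02)
    expect_lt(rej, 0.09)
  })
})

test_that("calibration slope recovers 1 for calibrated forecasts", {
  withr::with_seed(13, {
    p <- runif(1e4, 0.05, 0.95)
    o <- rbinom(1e4, 1, p)
    res <- calibration_slope(p, o)
    expect_true(res$estimable)
    expect_lt(res$conf.low, 1)
    expect_gt(res$conf.high, 1)
  })
  # complete separation is flagged, not estimated
  sep <- calibration_slope(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_false(sep$estimable)
  expect_true(is.na(sep$estimate))
  expect_error(calibration_slope(rep(0.3, 4), c(0, 1, 0, 1)), "variation")
  expect_error(calibration_slope(c(0.2, 0.8), c(1, 1)), "both outcome classes")
  expect_warning(calibration_slope(c(0, 0.6, 0.4, 1), c(1, 0, 1, 0)),
                 "clipped")
})

test_that("AUC is the Mann-Whitney probability with a logit-scale CI", {
  expect_equal(auc(c(0.2, 0.8), c(0, 1))$estimate, 1)
  perfect <- auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(perfect$estimate, 1)
  expect_true(is.na(perfect$conf.low))  # no CI at the boundary
  # ties get midrank treatment
  expect_equal(auc(c(0.5, 0.5), c(0, 1))$estimate, 0.5)
  expect_error(auc(c(0.2, 0.8), c(1, 1)), "both outcome classes")
  withr::with_seed(14, {
    p <- runif(2000)
    o <- rbinom(2000, 1, 0.4)  # independent of p
    res <- auc(p, o)
    expect_equal(res$estimate, 0.5, tolerance = 0.05)
    expect_true(res$conf.low < res$estimate & res$estimate < res$conf.high)
    # invariant under strictly increasing transforms of the forecasts
    expect_equal(auc(p^3, o)$estimate, res$estimate)
    # cross-check the point estimate against an independent implementation
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(o, p, quiet = TRUE,
                                            direction = "<")))
      expect_equal(res$estimate, ref, tolerance = 1e-12)
    }
  })
})

test_that("expected counts and the chi-squared comparison behave", {
  expect_equal(expected_significant(rep(0.5, 18)), 9)
  expect_error(expected_significant(numeric(0)), "at least one")
  same <- chisq_gof(15, 15, 20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ex <- chisq_gof(11, 15.0, 18)
  expect_equal(ex$statistic, 6.4, tolerance = 1e-12)
  expect_equal(ex$p_value, 0.011412036, tolerance = 1e-6)
  expect_lt(chisq_gof(13, 19.9, 21)$p_value, 1e-4)
  # two-cell symmetry
  a <- chisq_gof(11, 15, 18)
  b <- chisq_gof(7, 3, 18)
  expect_equal(a$statistic, b$statistic)
  # agreement with the stock goodness-of-fit machinery
  ref <- suppressWarnings(chisq.test(c(11, 7), p = c(15, 3) / 18))
  expect_equal(ex$statistic, unname(ref$statistic))
  expect_equal(ex$p_value, ref$p.value)
  expect_error(chisq_gof(1, 0, 10), "strictly inside")
  expect_error(chisq_gof(5, 10, 10), "strictly inside")
  expect_error(chisq_gof(11, 5, 10), "\\[0, n\\]")
})

test_that("paired score comparisons use the per-study differences", {
  a <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_warning(res <- compare_scores_paired(a, a), "Zero-variance")
  expect_equal(res$p_value, 1)
  withr::with_seed(15, {
    b <- rnorm(20)
    a2 <- b + rnorm(20, 1, 0.1)  # constant shift, small noise
    res2 <- compare_scores_paired(a2, b)
    expect_lt(res2$p_value, 1e-6)
    # oracle: the paired t reference computed by hand
    d <- a2 - b
    tstat <- mean(d) / (sd(d) / sqrt(20))
    expect_equal(res2$p_value, 2 * pt(-abs(tstat), df = 19), tolerance = 1e-12)
    perm <- compare_scores_paired(a2, b, method = "permutation", seed = 3)
    expect_lt(perm$p_value, 0.01)
    expect_error(compare_scores_paired(1:2, 1:3), "equal length")
  })
})
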