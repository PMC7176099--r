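test_that("flat-prior predictive follows mean theta_o, variance so2+sr2+2tau2", {
  p <- flat_predictive(0.2, 0.04, 0.02)
  expect_equal(p$mean, 0.2)
  expect_equal(p$variance, 0.06)  # naive model at tau = 0
  p2 <- flat_predictive(0.2, 0.04, 0.02, tau = 0.08)
  expect_equal(p2$variance, 0.04 + 0.02 + 2 * 0.0064)
  # variance strictly increasing in tau
  taus <- seq(0, 0.5, 0.05)
  v <- flat_predictive(0.2, 0.04, 0.02, tau = taus)$variance
  expect_true(all(diff(v) > 0))
  expect_error(flat_predictive(0.2, 0.04, -1), "positive")
})

test_that("empirical-Bayes g_hat clips at zero and vanishes for large tau", {
  expect_equal(g_hat(sqrt(0.01 + 0.04), 0.01, tau = 0.2), 0)  # boundary
  expect_equal(g_hat(0.2, 0.01), 3)
  expect_equal(g_hat(0.2, 0.01, tau = 100), 0)
  expect_true(all(g_hat(rnorm(20), 0.05, tau = 0.1) >= 0))
})

test_that("shrinkage factor matches g/(1+g) and its monotonicities", {
  expect_equal(shrinkage_factor(1, 0), 0)
  expect_equal(shrinkage_factor(1.96, 0), (1.96^2 - 1) / 1.96^2)
  expect_equal(shrinkage_factor(2, 1), 0.5)
  expect_equal(shrinkage_factor(0, 0), 0)      # degenerate but valid
  expect_equal(shrinkage_factor(1e8, 0), 1, tolerance = 1e-12)
  # identity with the empirical-Bayes estimate: s = g_hat/(1 + g_hat)
  theta <- c(0.05, 0.2, 0.4)
  so2 <- 0.02
  tau <- 0.05
  g <- g_hat(theta, so2, tau)
  s <- shrinkage_factor(theta / sqrt(so2), tau^2 / so2)
  expect_equal(s, g / (1 + g), tolerance = 1e-12)
  # nondecreasing in |t_o|, nonincreasing in d
  t <- seq(0.5, 5, 0.25)
  expect_true(all(diff(shrinkage_factor(t, 0.5)) >= 0))
  d <- seq(0, 3, 0.25)
  expect_true(all(diff(shrinkage_factor(2.5, d)) <= 0))
})

test_that("sceptical predictive shrinks the mean and is sharper than flat", {
  p <- sceptical_predictive(0.2, 0.01, 0.01)  # t_o = 2, s = 0.75
  expect_equal(p$mean, 0.15)
  expect_equal(p$variance, 0.0175)
  # fully shrunk branch: zero-mean forecast
  p0 <- sceptical_predictive(0.05, 0.01, 0.02, tau = 0.1)  # t_o^2 < 1 + d
  expect_equal(p0$mean, 0)
  expect_equal(p0$variance, 0.02 + 0.01)
  # strict sharpness ordering for finite t_o
  theta <- c(0.1, 0.3, 0.8)
  for (tau in c(0, 0.08)) {
    vf <- flat_predictive(theta, 0.02, 0.03, tau)$variance
    vs <- sceptical_predictive(theta, 0.02, 0.03, tau)$variance
    expect_true(all(vs < vf))
  }
})

test_that("test-statistic-scale predictive equals the z-scale one rescaled", {
  # spot values
  pf <- predictive_t(1.96, 1, 0, "flat")
  expect_equal(pf$mean, 1.96)
  expect_equal(pf$variance, 2)
  ps <- predictive_t(1.96, 1, 0, "sceptical")
  s <- shrinkage_factor(1.96, 0)
  expect_equal(ps$mean, s * 1.96)
  expect_equal(ps$variance, s + 1)
  # consistency contract across a grid of pairs and methods
  grid <- expand.grid(theta = c(0.05, 0.2, 0.5), no = c(20, 53, 100),
                      nr = c(30, 53, 150), tau = c(0, 0.08))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    so2 <- 1 / (g$no - 3)
    sr2 <- 1 / (g$nr - 3)
    t_o <- g$theta / sqrt(so2)
    cc <- so2 / sr2
    d <- g$tau^2 / so2
    for (prior in c("flat", "sceptical")) {
      z <- if (prior == "flat") {
        flat_predictive(g$theta, so2, sr2, g$tau)
      } else {
        sceptical_predictive(g$theta, so2, sr2, g$tau)
      }
      t <- predictive_t(t_o, cc, d, prior)
      expect_equal(t$mean, z$mean / sqrt(sr2), tolerance = 1e-12)
      expect_equal(t$variance, z$variance / sr2, tolerance = 1e-12)
    }
  }
  expect_error(predictive_t(1, c = 0), "positive")
  expect_error(predictive_t(1, 1, d = -1), "non-negative")
})

test_that("prediction intervals are central, monotone in tau, tanh-mapped", {
  pi1 <- prediction_interval(flat_predictive(0, 0.5, 0.5), level = 0.95)
  expect_equal(pi1$lower, -qnorm(0.975), tolerance = 1e-9)
  expect_equal(pi1$upper, qnorm(0.975), tolerance = 1e-9)
  pi2 <- prediction_interval(flat_predictive(0, 1, 1), level = 0.95)
  expect_equal(pi2$upper, qnorm(0.975) * sqrt(2), tolerance = 1e-9)
  expect_equal(pi2$upper, 2.771808, tolerance = 1e-6)
  # width nondecreasing in tau
  w <- vapply(seq(0, 0.3, 0.05), function(tau) {
    ci <- prediction_interval(flat_predictive(0.2, 0.04, 0.02, tau))
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(w) > 0))
  # correlation scale is the tanh image of the z-scale interval
  p <- flat_predictive(0.3, 0.05, 0.04)
  zi <- prediction_interval(p, 0.9)
  ri <- prediction_interval(p, 0.9, output_scale = "correlation")
  expect_equal(ri$lower, tanh(zi$lower))
  expect_equal(ri$upper, tanh(zi$upper))
  expect_error(prediction_interval(p, level = 1), "strictly inside")
  expect_error(
    prediction_interval(predictive_t(2, 1), output_scale = "correlation"),
    "fisher_z")
})

test_that("replication probability: the just-significant original case", {
  z <- qnorm(0.975)
  expect_equal(replication_probability(z, c = 1), 0.5, tolerance = 1e-12)
  p_scept <- replication_probability(z, c = 1, prior = "sceptical")
  # derived oracle: N(s z, s + 1) upper tail beyond z with s = 1 - 1/z^2
  s <- 1 - 1 / z^2
  expect_equal(p_scept, pnorm((z - s * z) / sqrt(s + 1), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(p_scept, 0.3494421, tolerance = 1e-6)
  expect_lt(p_scept, 0.5)
  expect_equal(replication_probability(50, c = 1), 1, tolerance = 1e-9)
  expect_error(replication_probability(-1, 1), "positive")
  expect_error(replication_probability(2, 1, alpha = 0), "strictly inside")
  # two-sided variant adds the (tiny) opposite tail
  p1 <- replication_probability(2.5, 1, two_sided = FALSE)
  p2 <- replication_probability(2.5, 1, two_sided = TRUE)
  expect_gt(p2, p1)
  expect_lt(p2 - p1, 1e-3)
})

test_that("replication probability is monotone in evidence and precision", {
  t <- seq(0.2, 5, 0.2)
  expect_true(all(diff(replication_probability(t, 1)) > 0))
  cs <- c(0.25, 0.5, 1, 2, 4)
  expect_true(all(diff(replication_probability(2.5, cs)) > 0))
  # sceptical: increasing once past the shrinkage threshold
  t2 <- seq(1.2, 5, 0.2)
  expect_true(all(diff(replication_probability(t2, 1, prior = "sceptical")) > 0))
})

test_that("required replication sample size matches a brute-force scan", {
  scan_oracle <- function(t_o, n_o, power, alpha, prior, tau) {
    nr <- 4:20000
    p <- replication_probability(t_o, variance_ratio(n_o, nr),
                                 relative_heterogeneity(tau, n_o),
                                 alpha, prior)
    ok <- nr[p >= power]
    if (length(ok) == 0) NA_integer_ else min(ok)
  }
  cases <- list(
    list(t_o = 2.8, n_o = 53, power = 0.8, prior = "flat", tau = 0),
    list(t_o = 2.8, n_o = 53, power = 0.8, prior = "flat", tau = 0.08),
    list(t_o = 3.2, n_o = 30, power = 0.9, prior = "sceptical", tau = 0),
    list(t_o = 2.2, n_o = 100, power = 0.6, prior = "sceptical", tau = 0.05)
  )
  for (cs in cases) {
    got <- required_replication_n(cs$t_o, cs$n_o, power = cs$power,
                                  prior = cs$prior, tau = cs$tau)
    expect_true(got$attainable)
    expect_equal(got$n_r,
                 scan_oracle(cs$t_o, cs$n_o, cs$power, 0.05, cs$prior, cs$tau))
  }
  # the canonical worked case
  expect_equal(required_replication_n(2.8, 53, 0.8)$n_r, 71L)
  # fully shrunk original can never be powered under the sceptical prior
  res <- required_replication_n(1, 50, power = 0.5, prior = "sceptical")
  expect_false(res$attainable)
  expect_true(is.na(res$n_r))
  # flat prior: supremum of power is pnorm(t_o / sqrt(1 + 2d))
  res2 <- required_replication_n(1, 50, power = 0.9, prior = "flat")
  expect_false(res2$attainable)
  expect_equal(res2$power, pnorm(1), tolerance = 1e-9)
})

test_that("canonical method labels map to prior and heterogeneity", {
  m <- rep_methods()
  expect_equal(m$label, c("N", "S", "H", "SH"))
  expect_equal(m$prior, c("flat", "sceptical", "flat", "sceptical"))
  expect_equal(m$tau, c(0, 0, default_tau, default_tau))
  expect_equal(rep_methods(labels = c("SH", "N"))$label, c("SH", "N"))
})
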