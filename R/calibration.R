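# Variance of CRPS/sigma for a calibrated standard-normal forecast:
# Var[h(Z)] with h(z) = z (2 pnorm(z) - 1) + 2 dnorm(z) - 1/sqrt(pi) and
# Z ~ N(0,1). Obtained once by adaptive quadrature (rel.tol 1e-13) and
# validated against a 2e7-draw Monte Carlo run; cached to 12 digits.
crps_var_const <- 0.162751579442

cal_result <- function(test, statistic, p_value, applicable = TRUE) {
  tibble::tibble(test = test, statistic = statistic, p_value = p_value,
                 applicable = applicable)
}

#' Spiegelhalter's z-test of binary forecast calibration
#'
#' Standardizes the Brier-score decomposition
#' `z = sum((o - p) * (1 - 2p)) / sqrt(sum((1 - 2p)^2 * p * (1 - p)))`, which
#' is approximately standard normal under perfect calibration; the returned
#' p-value is two-sided. Degenerate when the variance term is zero (e.g. all
#' forecasts exactly 0.5).
#'
#' @inheritParams brier
#' @return One-row tibble with `test`, `statistic`, `p_value`, `applicable`.
#' @examples
#' spiegelhalter_z(c(0.8, 0.4, 0.9), c(1, 0, 1))
#' @export
spiegelhalter_z <- function(prob, outcome) {
  check_binary_forecasts(prob, outcome)
  denom2 <- sum((1 - 2 * prob)^2 * prob * (1 - prob))
  if (denom2 <= 0) {
    abort("Spiegelhalter's z is degenerate: zero variance (e.g. all forecasts 0.5).")
  }
  z <- sum((outcome - prob) * (1 - 2 * prob)) / sqrt(denom2)
  cal_result("spiegelhalter_z", z, 2 * pnorm(-abs(z)))
}

#' Score-based calibration tests for normal forecasts
#'
#' Four tests of the null hypothesis that the observations are draws from
#' their stated normal predictive distributions, exploiting the known
#' distribution of proper scores under calibration:
#'
#' * `ls_z`: unconditional z-test on the logarithmic score, using
#'   `E[LS_i] = 0.5 * log(2 * pi * v_i) + 0.5` and `Var[LS_i] = 0.5`.
#' * `crps_z`: unconditional z-test on the CRPS, using
#'   `E[CRPS_i] = sqrt(v_i / pi)` and `Var[CRPS_i] = v_i * kappa` with
#'   `kappa` a universal constant (quadrature of the standard-normal case).
#' * `ls_reg`: regression of the individual LS on `log(sqrt(v_i))`;
#'   calibration implies intercept `0.5 * log(2 * pi) + 0.5`, slope 1 and a
#'   known residual variance of 0.5, so the coefficients are tested jointly
#'   by a 2-df known-variance Wald statistic.
#' * `crps_reg`: weighted (weights `1/v_i`) regression of the individual
#'   CRPS on `sqrt(v_i)`; calibration implies intercept 0, slope
#'   `1/sqrt(pi)` and known (weighted) residual variance `kappa`, again
#'   tested jointly by a 2-df known-variance Wald statistic.
#'
#' The regression tests need variation in the predictive variances; with
#' (numerically) constant `v_i` they are flagged not applicable. The four
#' p-values are typically summarized by their harmonic mean
#' ([harmonic_mean_p()]).
#'
#' @inheritParams scores
#' @return Four-row tibble with `test`, `statistic`, `p_value`, `applicable`.
#' @export
score_calibration_tests <- function(y, mean, variance) {
  check_score_args(y, mean, variance)
  n <- length(y)
  stopifnot(length(mean) == n, length(variance) == n)
  if (n < 3) abort("Need at least 3 forecasts for the calibration tests.")

  ls_i <- log_score(y, mean, variance)
  crps_i <- crps(y, mean, variance)

  z_ls <- sum(ls_i - (0.5 * log(2 * pi * variance) + 0.5)) / sqrt(n / 2)
  z_crps <- sum(crps_i - sqrt(variance / pi)) /
    sqrt(crps_var_const * sum(variance))
  out <- dplyr::bind_rows(
    cal_result("ls_z", z_ls, 2 * pnorm(-abs(z_ls))),
    cal_result("crps_z", z_crps, 2 * pnorm(-abs(z_crps)))
  )

  if (diff(range(variance)) < 1e-12 * base::mean(variance)) {
    return(dplyr::bind_rows(
      out,
      cal_result("ls_reg", NA_real_, NA_real_, FALSE),
      cal_result("crps_reg", NA_real_, NA_real_, FALSE)
    ))
  }

  # least-squares coefficients tested against their calibrated values with
  # the error variance fixed at its known null value (not estimated)
  wald2 <- function(X, y, null, error_var) {
    b <- drop(solve(crossprod(X), crossprod(X, y)))
    w <- drop(t(b - null) %*% crossprod(X) %*% (b - null)) / error_var
    c(w, pchisq(w, df = 2, lower.tail = FALSE))
  }
  w_ls <- wald2(cbind(1, 0.5 * log(variance)), ls_i,
                c(0.5 * log(2 * pi) + 0.5, 1), error_var = 0.5)
  # weights 1/v_i: rescale rows by 1/sqrt(v_i), leaving iid errors with
  # variance kappa under calibration
  w_crps <- wald2(cbind(1, sqrt(variance)) / sqrt(variance),
                  crps_i / sqrt(variance),
                  c(0, 1 / sqrt(pi)), error_var = crps_var_const)

  dplyr::bind_rows(
    out,
    cal_result("ls_reg", w_ls[1], w_ls[2]),
    cal_result("crps_reg", w_crps[1], w_crps[2])
  )
}

#' Harmonic mean of p-values
#'
#' The plain harmonic mean `k / sum(1/p)` used to summarize the four
#' score-based calibration tests into a single number; it always lies between
#' the smallest and largest input p-value.
#'
#' @param p P-values in (0, 1\].
#' @return A single probability.
#' @examples
#' harmonic_mean_p(c(0.01, 0.1, 0.1, 0.1))
#' @export
harmonic_mean_p <- function(p) {
  if (length(p) == 0) abort("Need at least one p-value.")
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in (0, 1].")
  length(p) / sum(1 / p)
}

#' Probability integral transform of a normal forecast
#'
#' The predictive CDF evaluated at the realized observation,
#' `pnorm((y - mean)/sqrt(variance))`. Under perfect calibration PIT values
#' are uniform on (0, 1); assess this with [ks_uniform()] or a histogram.
#'
#' @inheritParams scores
#' @return Probabilities in (0, 1).
#' @examples
#' pit(1.2, 0.5, 0.25)
#' @export
pit <- function(y, mean, variance) {
  check_score_args(y, mean, variance)
  pnorm((y - mean) / sqrt(variance))
}

#' Kolmogorov-Smirnov test of PIT uniformity
#'
#' One-sample KS test of the PIT values against Uniform(0, 1); `stats::ks.test()`
#' uses the exact small-sample null distribution for n < 100 and the
#' asymptotic one otherwise.
#'
#' @param pits PIT values in \[0, 1\].
#' @return One-row tibble with `test`, `statistic`, `p_value`, `applicable`.
#' @examples
#' ks_uniform(runif(20))
#' @export
ks_uniform <- function(pits) {
  if (length(pits) == 0) abort("Need at least one PIT value.")
  if (any(pits < 0 | pits > 1, na.rm = TRUE)) {
    abort("PIT values must lie in [0, 1].")
  }
  res <- suppressWarnings(ks.test(pits, "punif"))
  cal_result("ks_uniform", unname(res$statistic), res$p.value)
}

#' Logistic calibration slope of binary forecasts
#'
#' Regresses the outcomes on the logit-transformed forecast probabilities;
#' a well calibrated forecaster has slope about 1, slopes below (above) 1
#' indicate over- (under-) confident forecasts. With completely separated
#' forecasts the maximum likelihood estimate does not exist and the result is
#' flagged not estimable. Probabilities of exactly 0 or 1 are clipped to
#' `[1e-6, 1 - 1e-6]` with a warning.
#'
#' @inheritParams brier
#' @return One-row tibble with `estimate`, `conf.low`, `conf.high` (Wald 95%)
#'   and `estimable`.
#' @examples
#' set.seed(1)
#' p <- runif(50, 0.1, 0.9)
#' calibration_slope(p, rbinom(50, 1, p))
#' @export
calibration_slope <- function(prob, outcome) {
  check_binary_forecasts(prob, outcome)
  if (all(outcome == 0) || all(outcome == 1)) {
    abort("Calibration slope needs both outcome classes.")
  }
  eps <- 1e-6
  if (any(prob <= 0 | prob >= 1)) {
    warn("Probabilities of exactly 0 or 1 clipped to [1e-6, 1 - 1e-6].")
    prob <- pmin(pmax(prob, eps), 1 - eps)
  }
  lp <- qlogis(prob)
  if (diff(range(lp)) < 1e-12) {
    abort("Calibration slope needs variation in the forecast probabilities.")
  }
  separated <- max(lp[outcome == 0]) < min(lp[outcome == 1]) ||
    max(lp[outcome == 1]) < min(lp[outcome == 0])
  if (separated) {
    return(tibble::tibble(estimate = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_, estimable = FALSE))
  }
  fit <- suppressWarnings(glm(outcome ~ lp, family = binomial()))
  b <- coef(fit)[["lp"]]
  se <- sqrt(vcov(fit)["lp", "lp"])
  q <- qnorm(0.975)
  tibble::tibble(estimate = b, conf.low = b - q * se, conf.high = b + q * se,
                 estimable = TRUE)
}

#' Area under the ROC curve of binary forecasts
#'
#' Mann-Whitney AUC with midrank tie correction, i.e. the probability that a
#' randomly chosen significant replication received a higher forecast than a
#' randomly chosen non-significant one. The 95% Wald confidence interval uses
#' the DeLong variance, is built on the logit scale and back-transformed.
#' Forecasts that separate the classes completely give AUC 1 (or 0) without a
#' confidence interval.
#'
#' @inheritParams brier
#' @return One-row tibble with `estimate`, `conf.low`, `conf.high`.
#' @examples
#' auc(c(0.2, 0.6, 0.8), c(0, 1, 1))
#' @export
auc <- function(prob, outcome) {
  check_binary_forecasts(prob, outcome)
  x1 <- prob[outcome == 1]
  x0 <- prob[outcome == 0]
  if (length(x1) == 0 || length(x0) == 0) {
    abort("AUC needs both outcome classes.")
  }
  # midrank formulation of the Mann-Whitney statistic
  r <- rank(c(x1, x0))
  a <- (sum(r[seq_along(x1)]) - length(x1) * (length(x1) + 1) / 2) /
    (length(x1) * length(x0))
  if (a == 1 || a == 0) {
    return(tibble::tibble(estimate = a, conf.low = NA_real_,
                          conf.high = NA_real_))
  }
  # DeLong variance from placement values
  psi <- outer(x1, x0, function(u, v) (u > v) + 0.5 * (u == v))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  se <- sqrt(var(v10) / length(x1) + var(v01) / length(x0))
  q <- qnorm(0.975)
  se_logit <- se / (a * (1 - a))
  tibble::tibble(
    estimate = a,
    conf.low = plogis(qlogis(a) - q * se_logit),
    conf.high = plogis(qlogis(a) + q * se_logit)
  )
}

#' Expected number of significant replications
#'
#' The sum of the per-study forecast probabilities of a significant
#' replication — comparable to the observed count via [chisq_gof()].
#'
#' @param prob Forecast probabilities in \[0, 1\].
#' @return A single number.
#' @export
expected_significant <- function(prob) {
  if (length(prob) == 0) abort("Need at least one probability.")
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    abort("`prob` must lie in [0, 1].")
  }
  sum(prob)
}

#' Chi-squared comparison of observed and expected significant counts
#'
#' Two-cell (significant / not significant) goodness-of-fit statistic
#' `X2 = (O - E)^2 / E + (O - E)^2 / (n - E)` on 1 degree of freedom, without
#' continuity correction, with an upper-tail p-value. `E` may be fractional
#' (it is a sum of per-study probabilities).
#'
#' @param observed Observed count of significant replications, in \[0, n\].
#' @param expected Expected count, strictly inside (0, n).
#' @param n Number of study pairs.
#' @return One-row tibble with `test`, `statistic`, `p_value`, `applicable`.
#' @examples
#' chisq_gof(11, 15.0, 18)
#' @export
chisq_gof <- function(observed, expected, n) {
  stopifnot(length(observed) == 1, length(expected) == 1, length(n) == 1)
  if (observed < 0 || observed > n) abort("`observed` must lie in [0, n].")
  if (expected <= 0 || expected >= n) {
    abort("`expected` must lie strictly inside (0, n).")
  }
  x2 <- (observed - expected)^2 / expected +
    (observed - expected)^2 / (n - expected)
  cal_result("chisq_gof", x2, pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Paired comparison of two sets of per-study scores
#'
#' Tests whether two forecasting methods differ in predictive performance by
#' a two-sided paired test on the per-study score differences: a paired
#' t-test by default, or a sign-flip permutation test of the mean difference.
#'
#' @param scores_a,scores_b Per-study scores of the two methods, equal
#'   length `>= 3`.
#' @param method `"t"` or `"permutation"`.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Seed for the permutation draw (applied locally).
#' @return One-row tibble with `test`, `statistic` (mean difference a - b),
#'   `p_value`, `applicable`.
#' @export
compare_scores_paired <- function(scores_a, scores_b,
                                  method = c("t", "permutation"),
                                  n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  if (length(scores_a) != length(scores_b) || length(scores_a) < 3) {
    abort("`scores_a` and `scores_b` must have equal length >= 3.")
  }
  diffs <- scores_a - scores_b
  if (var(diffs) == 0) {
    warn("Zero-variance score differences; returning p = 1.")
    return(cal_result(paste0("paired_", method), base::mean(diffs), 1))
  }
  if (method == "t") {
    res <- t.test(scores_a, scores_b, paired = TRUE)
    cal_result("paired_t", base::mean(diffs), res$p.value)
  } else {
    obs <- base::mean(diffs)
    count <- withr::with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * length(diffs), replace = TRUE),
                      nrow = n_perm)
      sum(abs(drop(signs %*% diffs) / length(diffs)) >= abs(obs))
    })
    cal_result("paired_permutation", obs, (1 + count) / (1 + n_perm))
  }
}
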