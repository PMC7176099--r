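#' The four canonical forecasting methods
#'
#' Crossing the prior on the overall effect (flat vs. sceptical) with the
#' between-study heterogeneity (`tau = 0` vs. a positive default) gives the
#' four methods used throughout: `N` (naive: flat prior, no heterogeneity,
#' the classical prediction-interval model), `S` (shrinkage), `H`
#' (heterogeneity), and `SH` (shrinkage and heterogeneity).
#'
#' @param tau Heterogeneity standard deviation used by `H` and `SH`
#'   (Fisher-z scale); defaults to [default_tau].
#' @param labels Which of the four methods to return.
#' @return Tibble with columns `label`, `prior`, `tau`.
#' @examples
#' rep_methods()
#' @export
rep_methods <- function(tau = default_tau, labels = c("N", "S", "H", "SH")) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau >= 0)
  all <- tibble::tibble(
    label = c("N", "S", "H", "SH"),
    prior = c("flat", "sceptical", "flat", "sceptical"),
    tau = c(0, 0, tau, tau)
  )
  labels <- match.arg(labels, several.ok = TRUE)
  all[match(labels, all$label), ]
}

new_predictive <- function(mean, variance, scale) {
  if (any(variance <= 0, na.rm = TRUE)) abort("Predictive variance must be positive.")
  tibble::tibble(mean = mean, variance = variance, scale = scale)
}

#' Flat-prior predictive distribution of the replication estimate
#'
#' With a flat prior on the overall effect, the posterior predictive
#' distribution of the replication estimate on the Fisher-z scale is normal
#' with mean `theta_o` and variance `sigma_o2 + sigma_r2 + 2 * tau^2`. At
#' `tau = 0` this is the naive prediction-interval model of Patil and
#' colleagues: centred at the original estimate, no shrinkage.
#'
#' @param theta_o Original effect estimate(s), Fisher-z scale.
#' @param sigma_o2,sigma_r2 Variances of original and replication estimate
#'   (each `1/(n - 3)`), both positive.
#' @param tau Heterogeneity standard deviation, `>= 0`.
#' @return Tibble with columns `mean`, `variance`, `scale = "fisher_z"`.
#' @examples
#' flat_predictive(0.2, 0.04, 0.02)
#' @export
flat_predictive <- function(theta_o, sigma_o2, sigma_r2, tau = 0) {
  check_variances(sigma_o2, sigma_r2, tau)
  new_predictive(theta_o + 0 * sigma_r2,
                 sigma_o2 + sigma_r2 + 2 * tau^2,
                 "fisher_z")
}

#' Empirical-Bayes estimate of the sceptical prior's g parameter
#'
#' The sceptical prior is a zero-mean normal with variance
#' `g * (sigma_o2 + tau^2)` (a g-prior-type parametrization). Maximizing the
#' marginal likelihood of the original estimate gives
#' `g_hat = max(theta_o^2 / (sigma_o2 + tau^2) - 1, 0)`.
#'
#' @inheritParams flat_predictive
#' @return Non-negative numeric vector.
#' @export
g_hat <- function(theta_o, sigma_o2, tau = 0) {
  check_variances(sigma_o2, 1, tau)
  pmax(theta_o^2 / (sigma_o2 + tau^2) - 1, 0)
}

#' Evidence-based shrinkage factor
#'
#' `s = max(1 - (1 + d)/t_o^2, 0) = g_hat/(1 + g_hat)`: the factor by which
#' the original estimate is shrunk towards zero under the empirical-Bayes
#' sceptical prior. It grows with the evidence `|t_o|` in the original study
#' (`s -> 1` as `t_o -> Inf`) and falls with the relative heterogeneity `d`;
#' below `t_o^2 <= 1 + d` it clips at 0 and the forecast degenerates to a
#' zero-mean distribution. For `d = 0` this is the classical optimal-shrinkage
#' factor `1 - 1/t_o^2`.
#'
#' @param t_o Original test statistic(s) `theta_o / sigma_o`.
#' @param d Relative heterogeneity `tau^2 / sigma_o2`, `>= 0`.
#' @return Shrinkage factor(s) in \[0, 1\]. `t_o = 0` gives 0, not an error.
#' @examples
#' shrinkage_factor(1.96, 0)
#' @export
shrinkage_factor <- function(t_o, d = 0) {
  if (any(d < 0, na.rm = TRUE)) abort("`d` must be non-negative.")
  s <- ifelse(t_o == 0, 0, pmax(1 - (1 + d) / t_o^2, 0))
  pmin(s, 1)
}

#' Sceptical-prior predictive distribution of the replication estimate
#'
#' Under the empirical-Bayes sceptical prior the predictive distribution on
#' the Fisher-z scale is normal with mean `s * theta_o` and variance
#' `s * (sigma_o2 + tau^2) + sigma_r2 + tau^2`, with `s` the
#' [shrinkage_factor()]. Because `s <= 1`, this forecast is always sharper
#' than the flat-prior one.
#'
#' @inheritParams flat_predictive
#' @return Tibble with columns `mean`, `variance`, `scale = "fisher_z"`.
#' @examples
#' sceptical_predictive(0.2, 0.01, 0.01)
#' @export
sceptical_predictive <- function(theta_o, sigma_o2, sigma_r2, tau = 0) {
  check_variances(sigma_o2, sigma_r2, tau)
  s <- shrinkage_factor(theta_o / sqrt(sigma_o2), tau^2 / sigma_o2)
  new_predictive(s * theta_o,
                 s * (sigma_o2 + tau^2) + sigma_r2 + tau^2,
                 "fisher_z")
}

#' Predictive distribution of the replication test statistic
#'
#' The Fisher-z-scale predictive rescaled by `1/sigma_r`, so that it depends
#' only on the relative quantities `t_o`, `c` and `d`: flat prior
#' `N(sqrt(c) * t_o, 1 + c * (1 + 2 * d))`; sceptical prior
#' `N(s * sqrt(c) * t_o, s * c * (1 + d) + 1 + c * d)`.
#'
#' @param t_o Original test statistic(s).
#' @param c Variance ratio `sigma_o2 / sigma_r2`, positive.
#' @param d Relative heterogeneity, `>= 0`.
#' @param prior `"flat"` or `"sceptical"`.
#' @return Tibble with columns `mean`, `variance`, `scale = "test_statistic"`.
#' @examples
#' predictive_t(1.96, c = 1, d = 0, prior = "sceptical")
#' @export
predictive_t <- function(t_o, c, d = 0, prior = c("flat", "sceptical")) {
  prior <- match.arg(prior)
  if (any(c <= 0, na.rm = TRUE)) abort("`c` must be positive.")
  if (any(d < 0, na.rm = TRUE)) abort("`d` must be non-negative.")
  if (prior == "flat") {
    new_predictive(sqrt(c) * t_o, 1 + c * (1 + 2 * d), "test_statistic")
  } else {
    s <- shrinkage_factor(t_o, d)
    new_predictive(s * sqrt(c) * t_o, s * c * (1 + d) + 1 + c * d,
                   "test_statistic")
  }
}

#' Attach per-pair predictive distributions to a study-pair table
#'
#' The data-frame-first verb behind all evaluation: for each row it computes
#' the Fisher-z quantities (`theta_o`, `sigma_o2`, `sigma_r2`, `t_o`) and the
#' predictive mean and variance of the replication estimate under the given
#' prior and heterogeneity.
#'
#' @param pairs Data frame of study pairs (see [validate_pairs()]).
#' @param prior `"flat"` or `"sceptical"`.
#' @param tau Heterogeneity standard deviation, `>= 0`.
#' @return The input with columns `theta_o`, `sigma_o2`, `sigma_r2`, `t_o`,
#'   `pred_mean`, `pred_var` appended (Fisher-z scale).
#' @examples
#' simulate_pairs(3, seed = 1) |> predict_replication(prior = "sceptical")
#' @export
predict_replication <- function(pairs, prior = c("flat", "sceptical"), tau = 0) {
  prior <- match.arg(prior)
  pairs <- validate_pairs(pairs)
  out <- dplyr::mutate(
    pairs,
    theta_o = fisher_z(.data$ro),
    sigma_o2 = z_variance(.data$no),
    sigma_r2 = z_variance(.data$nr),
    t_o = .data$theta_o / sqrt(.data$sigma_o2)
  )
  pred <- if (prior == "flat") {
    flat_predictive(out$theta_o, out$sigma_o2, out$sigma_r2, tau)
  } else {
    sceptical_predictive(out$theta_o, out$sigma_o2, out$sigma_r2, tau)
  }
  out$pred_mean <- pred$mean
  out$pred_var <- pred$variance
  out
}

#' Central prediction interval of a normal predictive distribution
#'
#' @param pred Tibble of predictive distributions (columns `mean`,
#'   `variance`, `scale`) as returned by e.g. [flat_predictive()].
#' @param level Coverage level in (0, 1).
#' @param output_scale `"fisher_z"` (as computed) or `"correlation"`, which
#'   maps both endpoints through `tanh`; the map is monotone, so coverage is
#'   unchanged. Only Fisher-z-scale predictives can be mapped to correlations.
#' @return Tibble with columns `lower`, `upper`.
#' @examples
#' flat_predictive(0.2, 0.04, 0.02) |> prediction_interval()
#' @export
prediction_interval <- function(pred, level = 0.95,
                                output_scale = c("fisher_z", "correlation")) {
  output_scale <- match.arg(output_scale)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single probability strictly inside (0, 1).")
  }
  q <- qnorm((1 + level) / 2)
  lower <- pred$mean - q * sqrt(pred$variance)
  upper <- pred$mean + q * sqrt(pred$variance)
  if (output_scale == "correlation") {
    if (!all(pred$scale == "fisher_z")) {
      abort("Correlation-scale intervals need a fisher_z-scale predictive.")
    }
    lower <- tanh(lower)
    upper <- tanh(upper)
  }
  tibble::tibble(lower = lower, upper = upper)
}

# Tail probability of a significant same-direction replication, without the
# t_o > 0 gate (used internally where t_o = 0 is a valid degenerate case).
repl_prob_impl <- function(t_o, c, d, alpha, prior, two_sided = FALSE) {
  pred <- predictive_t(t_o, c, d, prior)
  z <- qnorm(1 - alpha / 2)
  p <- pnorm(z, pred$mean, sqrt(pred$variance), lower.tail = FALSE)
  if (two_sided) {
    p <- p + pnorm(-z, pred$mean, sqrt(pred$variance))
  }
  p
}

#' Probability of a significant replication in the original's direction
#'
#' Under the predictive distribution of the replication test statistic, the
#' probability that the replication is two-sided significant at level
#' `alpha` *and* has the same sign as the (oriented) original, i.e.
#' `P(t_r > z_(alpha/2))`. With a just-significant original
#' (`t_o = z_0.025`), equal precision (`c = 1`) and no heterogeneity this is
#' exactly 0.5 under the flat prior, and lower still under the sceptical
#' prior. Set `two_sided = TRUE` to also count the (usually negligible)
#' opposite-direction tail `P(t_r < -z_(alpha/2))`.
#'
#' @param t_o Original test statistic(s), strictly positive (orient first).
#' @param c Variance ratio, positive.
#' @param d Relative heterogeneity, `>= 0`.
#' @param alpha Two-sided significance level in (0, 1).
#' @param prior `"flat"` or `"sceptical"`.
#' @param two_sided Also count significance in the opposite direction?
#' @return Probabilities in (0, 1).
#' @examples
#' replication_probability(qnorm(0.975), c = 1)
#' @export
replication_probability <- function(t_o, c, d = 0, alpha = 0.05,
                                    prior = c("flat", "sceptical"),
                                    two_sided = FALSE) {
  prior <- match.arg(prior)
  if (any(t_o <= 0, na.rm = TRUE)) {
    abort("`t_o` must be positive; orient the pair first (see `orient_pairs()`).")
  }
  if (!is.numeric(alpha) || any(alpha <= 0 | alpha >= 1)) {
    abort("`alpha` must lie strictly inside (0, 1).")
  }
  repl_prob_impl(t_o, c, d, alpha, prior, two_sided)
}

# Supremum of the replication probability over the replication sample size
# (the c -> Inf limit); approached but never attained.
power_limit <- function(t_o, d, alpha, prior) {
  if (prior == "flat") {
    pnorm(t_o / sqrt(1 + 2 * d))
  } else {
    s <- shrinkage_factor(t_o, d)
    if (s == 0) {
      if (d > 0) 0.5 else alpha / 2
    } else {
      pnorm(s * t_o / sqrt(s * (1 + d) + d))
    }
  }
}

#' Replication sample size for a target replication probability
#'
#' Smallest integer replication sample size `n_r >= 4` whose probability of a
#' significant same-direction replication (see [replication_probability()])
#' reaches `power`. The search brackets on the continuous relaxation and then
#' verifies integer minimality locally. Because the replication probability
#' has a finite supremum as `n_r -> Inf` (e.g. `pnorm(t_o / sqrt(1 + 2 d))`
#' under the flat prior), some targets are unattainable at any sample size;
#' this is reported rather than an error. In particular a fully shrunk
#' original (`s = 0` under the sceptical prior) can never be powered.
#'
#' @param t_o Original test statistic, positive scalar (orient first).
#' @param n_o Original sample size, `> 3`.
#' @param power Target probability in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param prior `"flat"` or `"sceptical"`.
#' @param tau Heterogeneity standard deviation, `>= 0`.
#' @return One-row tibble with `n_r` (integer or `NA`), `power` (achieved at
#'   `n_r`, or the supremum when unattainable) and `attainable` (logical).
#' @examples
#' required_replication_n(2.8, n_o = 53, power = 0.8)
#' @export
required_replication_n <- function(t_o, n_o, power = 0.8, alpha = 0.05,
                                   prior = c("flat", "sceptical"), tau = 0) {
  prior <- match.arg(prior)
  stopifnot(length(t_o) == 1, length(n_o) == 1)
  if (!is.numeric(power) || power <= 0 || power >= 1) {
    abort("`power` must lie strictly inside (0, 1).")
  }
  if (t_o <= 0) abort("`t_o` must be positive; orient the pair first.")
  d <- relative_heterogeneity(tau, n_o)
  pow <- function(n_r) {
    repl_prob_impl(t_o, variance_ratio(n_o, n_r), d, alpha, prior)
  }
  n_max <- 1e7
  if (power_limit(t_o, d, alpha, prior) < power || pow(n_max) < power) {
    return(tibble::tibble(n_r = NA_integer_,
                          power = power_limit(t_o, d, alpha, prior),
                          attainable = FALSE))
  }
  lo <- 4L
  hi <- n_max
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (pow(mid) >= power) hi <- mid else lo <- mid
  }
  # local fix-up in case of slight non-monotonicity near the crossing
  cand <- seq.int(max(4L, hi - 3L), hi)
  hi <- min(cand[pow(cand) >= power])
  tibble::tibble(n_r = as.integer(hi), power = pow(hi), attainable = TRUE)
}

check_variances <- function(sigma_o2, sigma_r2, tau) {
  if (any(sigma_o2 <= 0, na.rm = TRUE)) abort("`sigma_o2` must be positive.")
  if (any(sigma_r2 <= 0, na.rm = TRUE)) abort("`sigma_r2` must be positive.")
  if (any(tau < 0, na.rm = TRUE)) abort("`tau` must be non-negative.")
  invisible(NULL)
}
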