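#' Proper scores for normal predictive distributions
#'
#' Per-forecast proper scoring rules for a normal predictive `N(mean,
#' variance)` evaluated at an observation `y`, all negatively oriented
#' (smaller is better):
#'
#' * `log_score()`: the negative log predictive density,
#'   `0.5 * log(2 * pi * v) + (y - m)^2 / (2 * v)`.
#' * `quadratic_score()`: the density formulation `-2 * f(y) + integral(f^2)`,
#'   which for a normal is `-2 * f(y) + 1 / (2 * sqrt(pi * v))`.
#' * `crps()`: the continuous ranked probability score, in closed form
#'   `sqrt(v) * (z * (2 * pnorm(z) - 1) + 2 * dnorm(z) - 1 / sqrt(pi))` with
#'   `z = (y - m)/sqrt(v)`.
#'
#' All are vectorized over forecasts and observations; extreme values are
#' reported as-is (no truncation).
#'
#' @param y Observed value(s).
#' @param mean,variance Predictive mean(s) and variance(s) (`variance > 0`).
#' @return Numeric vector of scores; `crps()` is always non-negative.
#' @examples
#' log_score(0, 0, 1)
#' crps(0, 0, 1)
#' @name scores
NULL

check_score_args <- function(y, mean, variance) {
  if (any(variance <= 0, na.rm = TRUE)) abort("`variance` must be positive.")
  invisible(NULL)
}

#' @rdname scores
#' @export
log_score <- function(y, mean, variance) {
  check_score_args(y, mean, variance)
  0.5 * log(2 * pi * variance) + (y - mean)^2 / (2 * variance)
}

#' @rdname scores
#' @export
quadratic_score <- function(y, mean, variance) {
  check_score_args(y, mean, variance)
  -2 * dnorm(y, mean, sqrt(variance)) + 1 / (2 * sqrt(pi * variance))
}

#' @rdname scores
#' @export
crps <- function(y, mean, variance) {
  check_score_args(y, mean, variance)
  sd <- sqrt(variance)
  z <- (y - mean) / sd
  sd * (z * (2 * pnorm(z) - 1) + 2 * dnorm(z) - 1 / sqrt(pi))
}

#' Mean proper scores of a set of normal forecasts
#'
#' Arithmetic means of the per-forecast quadratic, logarithmic and continuous
#' ranked probability scores — the summary used to rank forecasting methods.
#'
#' @inheritParams scores
#' @return One-row tibble with columns `qs`, `ls`, `crps`.
#' @examples
#' mean_scores(c(0.1, -0.2), mean = c(0, 0), variance = c(1, 1))
#' @export
mean_scores <- function(y, mean, variance) {
  if (length(y) == 0) abort("Need at least one forecast-observation pair.")
  stopifnot(length(mean) == length(y), length(variance) == length(y))
  tibble::tibble(
    qs = base::mean(quadratic_score(y, mean, variance)),
    ls = base::mean(log_score(y, mean, variance)),
    crps = base::mean(crps(y, mean, variance))
  )
}

check_binary_forecasts <- function(prob, outcome) {
  if (length(prob) == 0 || length(prob) != length(outcome)) {
    abort("`prob` and `outcome` must have equal positive length.")
  }
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    abort("`prob` must lie in [0, 1].")
  }
  if (!all(outcome %in% c(0, 1))) abort("`outcome` must be 0/1.")
  invisible(NULL)
}

#' Mean Brier score of binary forecasts
#'
#' `mean((prob - outcome)^2)`; 0 for perfect forecasts, 0.25 for the
#' uninformative constant forecast 0.5.
#'
#' @param prob Forecast probabilities in \[0, 1\].
#' @param outcome Observed binary outcomes (0/1).
#' @return A single number in \[0, 1\].
#' @examples
#' brier(c(0.8, 0.4), c(1, 0))
#' @export
brier <- function(prob, outcome) {
  check_binary_forecasts(prob, outcome)
  base::mean((prob - outcome)^2)
}

#' Mean normalized Brier score
#'
#' `(BS0 - BS)/BS0`, where `BS0` is the Brier score of the baseline that
#' forecasts the observed base rate for every study. Positive values mean the
#' forecasts beat the base-rate baseline; the normalization makes models
#' comparable across projects with different proportions of significant
#' replications. Undefined when all outcomes are identical (`BS0 = 0`).
#'
#' @inheritParams brier
#' @return A single number `<= 1`.
#' @examples
#' brier_normalized(c(0.8, 0.4), c(1, 0))
#' @export
brier_normalized <- function(prob, outcome) {
  check_binary_forecasts(prob, outcome)
  base_rate <- base::mean(outcome)
  if (base_rate == 0 || base_rate == 1) {
    abort("Normalized Brier score is undefined when all outcomes are identical.")
  }
  bs0 <- base::mean((base_rate - outcome)^2)
  (bs0 - brier(prob, outcome)) / bs0
}
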