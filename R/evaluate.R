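na_row <- function(...) tibble::tibble(...)

quiet_try <- function(expr, fallback) {
  tryCatch(suppressWarnings(expr), error = function(e) fallback)
}

#' Evaluate forecasting methods on a replication project
#'
#' The end-to-end evaluation: pairs are oriented so each original effect is
#' non-negative, per-pair normal predictive distributions of the replication
#' estimate are built on the Fisher-z scale for every method, and the full
#' battery of forecast-quality measures is computed — mean proper scores
#' (QS/LS/CRPS) with the harmonic-mean p-value of the four score-based
#' calibration tests, prediction-interval coverage, PIT values with a KS
#' uniformity test, probability-of-significance forecasts with observed and
#' expected significant counts and a chi-squared comparison, Brier and
#' normalized Brier scores with Spiegelhalter's z-test, the logistic
#' calibration slope, and the AUC.
#'
#' A replication counts as successful when it is two-sided significant at
#' `alpha` *with the same sign* as the oriented original (`t_r >
#' z_(alpha/2)`); the forecast probabilities use the matching one-tailed
#' definition (see [replication_probability()]).
#'
#' If a `pm_belief` column with non-missing values is present, those
#' externally elicited probabilities are evaluated with the binary-forecast
#' metrics under the method label `"PM"`.
#'
#' Measures that need more data than provided (calibration tests below 3
#' pairs, slope/AUC with single-class outcomes, separation) are reported as
#' `NA` / not estimable rather than failing the whole evaluation.
#'
#' @param pairs Study-pair table with observed replications (column `rr`).
#' @param methods Tibble of methods as produced by [rep_methods()].
#' @param alpha Two-sided significance level defining "success".
#' @param level Prediction-interval coverage level.
#' @param quiet Suppress orientation/evaluation messages?
#' @return An object of class `rep_evaluation`: a list with `summary` (one
#'   row per method), `calibration_tests`, `forecasts` (one row per pair and
#'   method) and metadata; see [tidy.rep_evaluation()].
#' @examples
#' simulate_pairs(20, seed = 7) |> evaluate_project() |> tidy()
#' @export
evaluate_project <- function(pairs, methods = rep_methods(), alpha = 0.05,
                             level = 0.95, quiet = FALSE) {
  stopifnot(is.data.frame(methods),
            all(c("label", "prior", "tau") %in% names(methods)))
  pairs <- validate_pairs(pairs, require_rr = TRUE)
  n <- nrow(pairs)
  if (n < 2) abort("Need at least 2 study pairs to evaluate.")
  pairs <- orient_pairs(pairs, quiet = quiet)
  n_flipped <- attr(pairs, "n_flipped")
  zcrit <- qnorm(1 - alpha / 2)

  forecasts <- purrr::pmap(methods, function(label, prior, tau) {
    aug <- predict_replication(pairs, prior = prior, tau = tau)
    theta_r <- fisher_z(aug$rr)
    sd_r <- sqrt(aug$sigma_r2)
    ci <- prediction_interval(
      new_predictive(aug$pred_mean, aug$pred_var, "fisher_z"), level = level)
    tibble::tibble(
      study = aug$study,
      method = label,
      theta_r = theta_r,
      t_r = theta_r / sd_r,
      pred_mean = aug$pred_mean,
      pred_var = aug$pred_var,
      lower = ci$lower,
      upper = ci$upper,
      covered = theta_r >= ci$lower & theta_r <= ci$upper,
      pit = pit(theta_r, aug$pred_mean, aug$pred_var),
      p_sig = pnorm(zcrit, aug$pred_mean / sd_r, sqrt(aug$pred_var) / sd_r,
                    lower.tail = FALSE),
      sig = as.numeric(theta_r / sd_r > zcrit),
      qs = quadratic_score(theta_r, aug$pred_mean, aug$pred_var),
      ls = log_score(theta_r, aug$pred_mean, aug$pred_var),
      crps = crps(theta_r, aug$pred_mean, aug$pred_var)
    )
  })
  forecasts <- dplyr::bind_rows(forecasts)
  observed <- sum(forecasts$sig[forecasts$method == methods$label[1]])

  cal_tests <- purrr::map(methods$label, function(lab) {
    f <- forecasts[forecasts$method == lab, ]
    res <- quiet_try(
      score_calibration_tests(f$theta_r, f$pred_mean, f$pred_var),
      cal_result(c("ls_z", "crps_z", "ls_reg", "crps_reg"),
                 NA_real_, NA_real_, FALSE))
    res$method <- lab
    res
  })
  cal_tests <- dplyr::bind_rows(cal_tests)

  binary_block <- function(p, o) {
    sp <- quiet_try(spiegelhalter_z(p, o),
                    cal_result("spiegelhalter_z", NA_real_, NA_real_, FALSE))
    cs <- quiet_try(calibration_slope(p, o),
                    tibble::tibble(estimate = NA_real_, conf.low = NA_real_,
                                   conf.high = NA_real_, estimable = FALSE))
    au <- quiet_try(auc(p, o),
                    tibble::tibble(estimate = NA_real_, conf.low = NA_real_,
                                   conf.high = NA_real_))
    e <- expected_significant(p)
    ch <- quiet_try(chisq_gof(sum(o), e, length(o)),
                    cal_result("chisq_gof", NA_real_, NA_real_, FALSE))
    tibble::tibble(
      observed = sum(o), expected = e, chisq_p = ch$p_value,
      bs = brier(p, o),
      bs_norm = quiet_try(brier_normalized(p, o), NA_real_),
      spiegelhalter = sp$statistic, spiegelhalter_p = sp$p_value,
      slope = cs$estimate, slope_low = cs$conf.low, slope_high = cs$conf.high,
      slope_estimable = cs$estimable,
      auc = au$estimate, auc_low = au$conf.low, auc_high = au$conf.high
    )
  }

  summary <- purrr::map(methods$label, function(lab) {
    f <- forecasts[forecasts$method == lab, ]
    ks <- quiet_try(ks_uniform(f$pit),
                    cal_result("ks_uniform", NA_real_, NA_real_, FALSE))
    ct <- cal_tests[cal_tests$method == lab & cal_tests$applicable, ]
    p_cal <- if (nrow(ct) > 0 && !anyNA(ct$p_value)) {
      harmonic_mean_p(ct$p_value)
    } else {
      NA_real_
    }
    dplyr::bind_cols(
      tibble::tibble(method = lab),
      mean_scores(f$theta_r, f$pred_mean, f$pred_var),
      tibble::tibble(p_cal = p_cal,
                     coverage = base::mean(f$covered),
                     ks_p = ks$p_value),
      binary_block(f$p_sig, f$sig)
    )
  })
  summary <- dplyr::bind_rows(summary)

  pm <- NULL
  if ("pm_belief" %in% names(pairs) && any(!is.na(pairs$pm_belief))) {
    if (anyNA(pairs$pm_belief)) {
      warn("Some `pm_belief` values are missing; PM metrics use all pairs and treat NA as not evaluable.")
    }
    keep <- !is.na(pairs$pm_belief)
    o <- forecasts$sig[forecasts$method == methods$label[1]][keep]
    pm <- dplyr::bind_cols(tibble::tibble(method = "PM"),
                           binary_block(pairs$pm_belief[keep], o))
  } else if ("pm_belief" %in% names(pairs) && !quiet) {
    inform("No prediction-market beliefs present; PM metrics skipped.")
  }

  structure(
    list(summary = summary, pm = pm, calibration_tests = cal_tests,
         forecasts = forecasts,
         meta = list(n = n, alpha = alpha, level = level,
                     n_flipped = n_flipped, observed = observed,
                     methods = methods)),
    class = "rep_evaluation"
  )
}

#' @export
print.rep_evaluation <- function(x, ...) {
  cat("Replication-project forecast evaluation\n")
  cat(sprintf("  %d study pairs; alpha = %g, PI level = %g; %d pair(s) sign-flipped\n",
              x$meta$n, x$meta$alpha, x$meta$level, x$meta$n_flipped))
  cat(sprintf("  observed significant replications: %d\n\n", x$meta$observed))
  print(tidy(x), width = Inf)
  invisible(x)
}

#' Tidy a replication-project evaluation
#'
#' One row per forecasting method with the full set of evaluation measures
#' (mean scores, harmonic-mean calibration p, coverage, KS p, expected and
#' observed significant counts, Brier scores, Spiegelhalter z, calibration
#' slope, AUC). Prediction-market forecasts, when present, appear as a `PM`
#' row with binary-forecast measures only.
#'
#' @param x A [evaluate_project()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rep_evaluation <- function(x, ...) {
  dplyr::bind_rows(x$summary, x$pm)
}

#' One-line summary of an evaluation
#'
#' @param x A [evaluate_project()] result.
#' @param ... Unused.
#' @return One-row tibble with the project-level metadata.
#' @export
glance.rep_evaluation <- function(x, ...) {
  tibble::tibble(n = x$meta$n, alpha = x$meta$alpha, level = x$meta$level,
                 n_flipped = x$meta$n_flipped, observed = x$meta$observed,
                 n_methods = nrow(x$meta$methods))
}

#' Prediction-interval coverage of one forecasting method
#'
#' Fraction of pairs whose Fisher-z replication estimate falls inside the
#' central prediction interval. The interval endpoints may equivalently be
#' mapped to the correlation scale: `tanh` is monotone, so coverage is
#' identical on either scale.
#'
#' @inheritParams predict_replication
#' @param level Interval coverage level in (0, 1).
#' @param quiet Suppress the orientation message?
#' @return A single proportion.
#' @examples
#' simulate_pairs(50, seed = 3) |> coverage(prior = "flat", tau = 0.08)
#' @export
coverage <- function(pairs, prior = c("flat", "sceptical"), tau = 0,
                     level = 0.95, quiet = TRUE) {
  pairs <- validate_pairs(pairs, require_rr = TRUE)
  pairs <- orient_pairs(pairs, quiet = quiet)
  aug <- predict_replication(pairs, prior = prior, tau = tau)
  theta_r <- fisher_z(aug$rr)
  ci <- prediction_interval(
    new_predictive(aug$pred_mean, aug$pred_var, "fisher_z"), level = level)
  base::mean(theta_r >= ci$lower & theta_r <= ci$upper)
}

#' Mean scores as a function of the heterogeneity parameter
#'
#' Recomputes the mean QS, LS and CRPS of the flat-prior (`H`-type) and
#' sceptical-prior (`SH`-type) forecasts over a grid of heterogeneity values
#' `tau`. Because optimizing a mean proper score is a valid estimation
#' method, the score-minimizing grid value doubles as a crude heterogeneity
#' estimate; the per-score argmin is attached as the `"argmin"` attribute.
#'
#' @param pairs Study-pair table with observed replications.
#' @param tau_grid Non-negative heterogeneity values to scan.
#' @param priors Which prior(s) to trace over the grid.
#' @param quiet Suppress the orientation message?
#' @return Tibble of class `rep_tau_sensitivity` with columns `prior`,
#'   `tau`, `qs`, `ls`, `crps`, and attribute `argmin`.
#' @examples
#' sens <- simulate_pairs(50, seed = 5) |> tau_sensitivity(seq(0, 0.2, 0.02))
#' attr(sens, "argmin")
#' @export
tau_sensitivity <- function(pairs, tau_grid,
                            priors = c("flat", "sceptical"), quiet = TRUE) {
  if (length(tau_grid) == 0) abort("`tau_grid` must be nonempty.")
  if (any(tau_grid < 0)) abort("`tau_grid` values must be non-negative.")
  priors <- match.arg(priors, several.ok = TRUE)
  pairs <- validate_pairs(pairs, require_rr = TRUE)
  pairs <- orient_pairs(pairs, quiet = quiet)
  grid <- tidyr::expand_grid(prior = priors, tau = sort(tau_grid))
  out <- purrr::pmap(grid, function(prior, tau) {
    aug <- predict_replication(pairs, prior = prior, tau = tau)
    theta_r <- fisher_z(aug$rr)
    dplyr::bind_cols(tibble::tibble(prior = prior, tau = tau),
                     mean_scores(theta_r, aug$pred_mean, aug$pred_var))
  })
  out <- dplyr::bind_rows(out)
  argmin <- out |>
    tidyr::pivot_longer(c("qs", "ls", "crps"),
                        names_to = "score", values_to = "mean_score") |>
    dplyr::group_by(.data$prior, .data$score) |>
    dplyr::slice_min(.data$mean_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("prior", "score", tau_min = "tau",
                  min_score = "mean_score")
  structure(out, argmin = argmin,
            class = c("rep_tau_sensitivity", class(out)))
}

# Serializable (JSON) form of an evaluation; NA -> explicit null.
as_report_list <- function(ev) {
  stopifnot(inherits(ev, "rep_evaluation"))
  na_null <- function(x) {
    if (is.data.frame(x)) {
      lapply(seq_len(nrow(x)), function(i) lapply(x[i, ], na_null))
    } else if (length(x) == 1 && is.na(x)) {
      NULL
    } else {
      x
    }
  }
  list(
    report_version = 1,
    n = ev$meta$n,
    alpha = ev$meta$alpha,
    level = ev$meta$level,
    n_flipped = ev$meta$n_flipped,
    observed_significant = ev$meta$observed,
    methods = na_null(tidy(ev)),
    calibration_tests = na_null(ev$calibration_tests)
  )
}
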