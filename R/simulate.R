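#' Simulate a synthetic replication project
#'
#' Generates original/replication study pairs from the hierarchical normal
#' model on the Fisher-z scale: an overall effect
#' `theta ~ N(effect_mean, effect_sd^2)`, study-specific effects
#' `theta_o, theta_r ~ N(theta, tau^2)` drawn independently, and estimates
#' `theta_hat_k ~ N(theta_k, 1/(n_k - 3))`; reported correlations are
#' `tanh(theta_hat_k)`.
#'
#' With `selection = TRUE` the generator emulates file-drawer publication
#' bias: the whole original-study triple `(theta, theta_o, theta_hat_o)` is
#' redrawn until the original estimate is two-sided significant at
#' `selection_alpha`, and only then are `theta_r` and `theta_hat_r` drawn
#' (unconditionally). Selected originals are therefore inflated relative to
#' their underlying effects — the pattern the shrinkage methods are built to
#' counteract.
#'
#' The defaults describe a modest social-science-like project: true effects
#' around `r = 0.2` with some spread, the package's default heterogeneity
#' [default_tau], original sample sizes uniform on 20..100, and replications
#' of equal size.
#'
#' @param n_pairs Number of study pairs, `>= 1`.
#' @param effect_mean,effect_sd Mean and standard deviation of the overall
#'   effect distribution (Fisher-z scale; `effect_sd >= 0`).
#' @param tau Between-study heterogeneity standard deviation, `>= 0`.
#' @param n_o_range Integer range (length 2) from which original sample sizes
#'   are drawn uniformly; both ends `>= 4`.
#' @param n_r_rule `"equal"` (replication sample size equals the original's)
#'   or `"multiplier"` (`n_r = max(4, round(n_r_factor * n_o))`).
#' @param n_r_factor Multiplier used when `n_r_rule = "multiplier"`.
#' @param selection Keep only significance-selected originals?
#' @param selection_alpha Two-sided selection threshold in (0, 1).
#' @param seed Integer seed applied locally (global RNG state untouched);
#'   `NULL` uses the current RNG stream.
#' @param keep_truth Also return the latent `theta`, `theta_o`, `theta_r`?
#' @return Tibble with columns `study`, `ro`, `no`, `rr`, `nr` (and the
#'   latent columns if requested).
#' @examples
#' simulate_pairs(5, seed = 42)
#' @export
simulate_pairs <- function(n_pairs,
                           effect_mean = 0.2,
                           effect_sd = 0.15,
                           tau = default_tau,
                           n_o_range = c(20L, 100L),
                           n_r_rule = c("equal", "multiplier"),
                           n_r_factor = 1,
                           selection = FALSE,
                           selection_alpha = 0.05,
                           seed = NULL,
                           keep_truth = FALSE) {
  n_r_rule <- match.arg(n_r_rule)
  stopifnot(length(n_pairs) == 1, n_pairs >= 1,
            effect_sd >= 0, tau >= 0, n_r_factor > 0,
            length(n_o_range) == 2, all(n_o_range >= 4),
            n_o_range[1] <= n_o_range[2])
  if (selection_alpha <= 0 || selection_alpha >= 1) {
    abort("`selection_alpha` must lie strictly inside (0, 1).")
  }
  run <- function() {
    n_pairs <- as.integer(n_pairs)
    no <- sample(seq.int(n_o_range[1], n_o_range[2]), n_pairs, replace = TRUE)
    nr <- switch(n_r_rule,
                 equal = no,
                 multiplier = pmax(4L, as.integer(round(n_r_factor * no))))
    so <- sqrt(z_variance(no))
    theta <- rnorm(n_pairs, effect_mean, effect_sd)
    theta_o <- rnorm(n_pairs, theta, tau)
    that_o <- rnorm(n_pairs, theta_o, so)
    if (selection) {
      zcrit <- qnorm(1 - selection_alpha / 2)
      todo <- which(abs(that_o / so) <= zcrit)
      iter <- 0L
      while (length(todo) > 0) {
        iter <- iter + 1L
        if (iter > 100000L) abort("Significance selection did not converge.")
        theta[todo] <- rnorm(length(todo), effect_mean, effect_sd)
        theta_o[todo] <- rnorm(length(todo), theta[todo], tau)
        that_o[todo] <- rnorm(length(todo), theta_o[todo], so[todo])
        todo <- todo[abs(that_o[todo] / so[todo]) <= zcrit]
      }
    }
    theta_r <- rnorm(n_pairs, theta, tau)
    that_r <- rnorm(n_pairs, theta_r, sqrt(z_variance(nr)))
    out <- tibble::tibble(
      study = sprintf("sim-%04d", seq_len(n_pairs)),
      ro = tanh(that_o),
      no = as.numeric(no),
      rr = tanh(that_r),
      nr = as.numeric(nr)
    )
    if (keep_truth) {
      out$theta <- theta
      out$theta_o <- theta_o
      out$theta_r <- theta_r
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Draw replication outcomes from a method's own predictive distributions
#'
#' Replaces the replication estimates by draws from the per-pair predictive
#' distribution of the given method: `theta_hat_r ~ N(pred_mean, pred_var)`
#' given each original. Forecasts evaluated against data generated this way
#' are perfectly calibrated *by construction*, which makes this the
#' reference generator for checking that every calibration test keeps its
#' nominal level (the "self-consistent" simulation).
#'
#' @param pairs Study-pair table; `rr` is ignored and overwritten.
#' @param prior,tau Forecasting method whose predictive is sampled.
#' @param seed Integer seed applied locally; `NULL` uses the current stream.
#' @return `pairs` with `rr` replaced by the simulated replication
#'   correlations.
#' @examples
#' simulate_pairs(5, seed = 1) |> simulate_replications(prior = "flat")
#' @export
simulate_replications <- function(pairs, prior = c("flat", "sceptical"),
                                  tau = 0, seed = NULL) {
  prior <- match.arg(prior)
  aug <- predict_replication(pairs, prior = prior, tau = tau)
  run <- function() {
    pairs$rr <- tanh(rnorm(nrow(aug), aug$pred_mean, sqrt(aug$pred_var)))
    pairs
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Read a study-pair CSV
#'
#' Expects a header with the mandatory columns `study, ro, no, rr, nr` and
#' optionally `pm_belief`; `rr` entries may be empty for pre-replication
#' (design-mode) rows. Gzip-compressed files are handled transparently. The
#' table is validated on read with row-level error messages.
#'
#' @param path Path to a `.csv` (or `.csv.gz`) file.
#' @return Validated tibble of study pairs.
#' @seealso [write_pairs_csv()]
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  pairs <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             study = readr::col_character(),
                             .default = readr::col_double()
                           ))
  validate_pairs(pairs)
}

#' Write a study-pair CSV
#'
#' Comma-separated UTF-8 with the fixed header
#' `study,ro,no,rr,nr,pm_belief`, missing values written as empty fields and
#' numbers at full (round-trip exact) precision. A `pm_belief` column is
#' added (empty) if absent so the schema is stable.
#'
#' @param pairs Study-pair table (may be empty).
#' @param path Output path.
#' @return `pairs`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  if (nrow(pairs) > 0) pairs <- validate_pairs(pairs)
  if (!"pm_belief" %in% names(pairs)) pairs$pm_belief <- NA_real_
  out <- pairs[, c(pair_columns, "pm_belief")]
  # serialize doubles at 17 significant digits so a read-back is bit-exact
  fmt <- function(x) {
    if (!is.double(x)) return(x)
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.double), fmt))
  readr::write_csv(out, path, na = "")
  invisible(pairs)
}
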