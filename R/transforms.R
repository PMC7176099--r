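#' Fisher z-transformation of a correlation coefficient
#'
#' The variance-stabilizing transformation `atanh(r)`. On this scale an
#' estimated correlation from `n` independent observations is asymptotically
#' normal with variance `1/(n - 3)` (see [z_variance()]), which is what makes
#' the closed-form predictive distributions in this package possible.
#'
#' @param r Numeric vector of correlations, each strictly inside (-1, 1).
#' @return Numeric vector on the Fisher-z scale.
#' @seealso [inverse_fisher_z()]
#' @examples
#' fisher_z(c(0, 0.5, -0.3))
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) abort("`r` must be numeric.")
  bad <- is.finite(r) & abs(r) >= 1
  if (any(bad, na.rm = TRUE) || any(!is.finite(r) & !is.na(r))) {
    abort("Correlations must lie strictly between -1 and 1.")
  }
  atanh(r)
}

#' Back-transform from the Fisher-z scale to a correlation
#'
#' @param z Numeric vector of finite Fisher-z values.
#' @return Correlations in (-1, 1); `tanh(z)`.
#' @examples
#' inverse_fisher_z(fisher_z(0.5))
#' @export
inverse_fisher_z <- function(z) {
  if (!is.numeric(z)) abort("`z` must be numeric.")
  if (any(!is.finite(z) & !is.na(z))) abort("`z` must be finite.")
  tanh(z)
}

#' Variance of a Fisher z-transformed correlation
#'
#' `1/(n - 3)`, the (asymptotic) variance of `atanh(r)` for a correlation
#' estimated from `n` observations. `n` may be a non-integer "effective"
#' sample size; values in (3, 4) are accepted with a warning, `n <= 3` is an
#' error because the variance would not be finite and positive.
#'
#' @param n Numeric vector of sample sizes, each `> 3`.
#' @return Numeric vector of variances.
#' @examples
#' z_variance(28)  # 1/25
#' @export
z_variance <- function(n) {
  if (!is.numeric(n)) abort("`n` must be numeric.")
  if (any(n <= 3, na.rm = TRUE)) {
    abort("Sample sizes must exceed 3 (variance 1/(n - 3) must be positive).")
  }
  if (any(n < 4, na.rm = TRUE)) {
    warn("Sample sizes below 4 give variances of 1 or more; interpret with care.")
  }
  1 / (n - 3)
}

#' Variance ratio c of original to replication estimate
#'
#' `c = sigma_o^2 / sigma_r^2 = (n_r - 3)/(n_o - 3)`: the precision of the
#' replication relative to the original. `c > 1` means the replication is the
#' more precise study.
#'
#' @param n_o,n_r Sample sizes (each `> 3`) of original and replication study.
#' @return Numeric vector of positive variance ratios.
#' @examples
#' variance_ratio(28, 53)  # replication twice as precise
#' @export
variance_ratio <- function(n_o, n_r) {
  z_variance(n_o) / z_variance(n_r)
}

#' Relative between-study heterogeneity d
#'
#' `d = tau^2 / sigma_o^2 = tau^2 * (n_o - 3)`: the heterogeneity variance
#' expressed in units of the original estimate's variance.
#'
#' @param tau Heterogeneity standard deviation on the Fisher-z scale, `>= 0`.
#' @param n_o Original-study sample size, `> 3`.
#' @return Numeric vector, `>= 0`.
#' @examples
#' relative_heterogeneity(0.08, 103)
#' @export
relative_heterogeneity <- function(tau, n_o) {
  if (!is.numeric(tau)) abort("`tau` must be numeric.")
  if (any(tau < 0, na.rm = TRUE)) abort("`tau` must be non-negative.")
  tau^2 / z_variance(n_o)
}

# Columns every study-pair table must carry.
pair_columns <- c("study", "ro", "no", "rr", "nr")

#' Validate a table of original/replication study pairs
#'
#' Checks the schema (`study`, `ro`, `no`, `rr`, `nr`, optional `pm_belief`)
#' and the row-level invariants: correlations strictly inside (-1, 1), sample
#' sizes above 3, prediction-market beliefs in \[0, 1\]. Missing `rr` is
#' allowed (pre-replication "design" use) unless `require_rr = TRUE`.
#'
#' @param pairs Data frame of study pairs.
#' @param require_rr Require an observed replication estimate in every row?
#' @return The validated pairs as a tibble, invisibly usable in a pipe.
#' @export
validate_pairs <- function(pairs, require_rr = FALSE) {
  if (!is.data.frame(pairs)) abort("`pairs` must be a data frame.")
  missing_cols <- setdiff(pair_columns, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("`pairs` is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  pairs <- tibble::as_tibble(pairs)
  row_fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad) > 0) {
      abort(paste0(what, " in row(s): ", paste(head(bad, 5), collapse = ", "),
                   if (length(bad) > 5) ", ..." else "", "."))
    }
  }
  row_fail(!is.na(pairs$ro) & abs(pairs$ro) >= 1,
           "`ro` outside (-1, 1)")
  row_fail(!is.na(pairs$rr) & abs(pairs$rr) >= 1,
           "`rr` outside (-1, 1)")
  row_fail(is.na(pairs$ro), "missing `ro`")
  row_fail(!is.na(pairs$no) & pairs$no <= 3, "`no` must exceed 3")
  row_fail(!is.na(pairs$nr) & pairs$nr <= 3, "`nr` must exceed 3")
  row_fail(is.na(pairs$no) | is.na(pairs$nr), "missing sample size")
  if (any(pairs$no < 4, na.rm = TRUE) || any(pairs$nr < 4, na.rm = TRUE)) {
    warn("Effective sample sizes below 4 present; variances are 1 or more.")
  }
  if ("pm_belief" %in% names(pairs)) {
    row_fail(!is.na(pairs$pm_belief) &
               (pairs$pm_belief < 0 | pairs$pm_belief > 1),
             "`pm_belief` outside [0, 1]")
  }
  if (require_rr) {
    row_fail(is.na(pairs$rr),
             "missing `rr` (evaluation needs observed replications; use the design tools instead)")
  }
  pairs
}

#' Orient study pairs so the original effect is non-negative
#'
#' Replication success "in the same direction as the original" is only well
#' defined after fixing a direction. This flips the sign of both `ro` and
#' `rr` in every row with `ro < 0` (rows with `ro` exactly 0 are left alone);
#' the operation is idempotent and is reported via a message and the
#' `n_flipped` attribute.
#'
#' @param pairs Data frame of study pairs (see [validate_pairs()]).
#' @param quiet Suppress the message about how many rows were flipped?
#' @return The oriented pairs (tibble) with attribute `n_flipped`.
#' @examples
#' pairs <- tibble::tibble(study = "a", ro = -0.3, no = 50, rr = -0.1, nr = 60)
#' orient_pairs(pairs)
#' @export
orient_pairs <- function(pairs, quiet = FALSE) {
  pairs <- validate_pairs(pairs)
  flip <- !is.na(pairs$ro) & pairs$ro < 0
  pairs$ro[flip] <- -pairs$ro[flip]
  pairs$rr[flip] <- -pairs$rr[flip]
  if (!quiet && any(flip)) {
    inform(paste0("Oriented ", sum(flip), " of ", nrow(pairs),
                  " pair(s) so that ro >= 0."))
  }
  attr(pairs, "n_flipped") <- sum(flip)
  pairs
}
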