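#' Default between-study heterogeneity
#'
#' The default heterogeneity standard deviation on the Fisher-z scale used by
#' the `H` and `SH` forecasting methods, `tau = 0.08`. It is chosen so that
#' the 95% range of the study-specific underlying correlations around an
#' overall effect of zero, [delta_of_tau()], is about the size of a medium
#' effect (`r = 0.3` in Cohen's classification) — deliberately modest, since
#' direct replications are matched to their originals as closely as possible.
#'
#' @format A single number, 0.08.
#' @seealso [delta_of_tau()], [tau_for_delta()], [cohen_effect_sizes]
#' @export
default_tau <- 0.08

#' Cohen's correlation effect-size anchors
#'
#' Small, medium and large correlation magnitudes (0.1, 0.3, 0.5), used as
#' reference lines when judging plausible heterogeneity via [delta_of_tau()].
#'
#' @format Named numeric vector of length 3.
#' @export
cohen_effect_sizes <- c(small = 0.1, medium = 0.3, large = 0.5)

#' Correlation-scale width of the 95% heterogeneity range
#'
#' Under the hierarchical model, 95% of the study-specific underlying effects
#' lie in `theta +/- z_0.025 * tau` on the Fisher-z scale. Back-transformed,
#' the width of that range is
#' `delta(tau) = tanh(theta + z_0.025 * tau) - tanh(theta - z_0.025 * tau)`.
#' Evaluated at `theta = 0` (the default, and the convention used to pick
#' [default_tau]) it is `2 * tanh(z_0.025 * tau)`, strictly increasing in
#' `tau` with range \[0, 2).
#'
#' @param tau Heterogeneity standard deviation(s), `>= 0` (Fisher-z scale).
#' @param theta Overall effect on the Fisher-z scale (default 0).
#' @return Correlation-scale width(s) in \[0, 2).
#' @examples
#' delta_of_tau(0.08)
#' @export
delta_of_tau <- function(tau, theta = 0) {
  if (any(tau < 0, na.rm = TRUE)) abort("`tau` must be non-negative.")
  z <- qnorm(0.975)
  tanh(theta + z * tau) - tanh(theta - z * tau)
}

#' Heterogeneity implied by a target correlation-scale width
#'
#' Inverse of [delta_of_tau()] at `theta = 0`, found by root-finding to
#' 1e-10: the `tau` whose 95% heterogeneity range on the correlation scale
#' has the requested width.
#'
#' @param width Target width strictly inside (0, 2).
#' @return Heterogeneity standard deviation on the Fisher-z scale.
#' @examples
#' tau_for_delta(0.3)  # a medium-effect-sized range
#' @export
tau_for_delta <- function(width) {
  if (!is.numeric(width) || length(width) != 1 ||
      width <= 0 || width >= 2) {
    abort("`width` must be a single value strictly inside (0, 2).")
  }
  upper <- 1
  while (delta_of_tau(upper) < width) upper <- upper * 2
  uniroot(function(tau) delta_of_tau(tau) - width,
          lower = 0, upper = upper, tol = 1e-10)$root
}
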