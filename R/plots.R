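#' Plot an evaluation: PIT histograms or prediction intervals
#'
#' `type = "pit"` draws per-method PIT histograms (flat under perfect
#' calibration) annotated with the KS uniformity p-value; `type =
#' "intervals"` draws original versus replication effect estimates on the
#' correlation scale with the vertical prediction interval of each pair.
#'
#' @param object A [evaluate_project()] result.
#' @param type `"pit"` or `"intervals"`.
#' @param bins Number of histogram bins for `type = "pit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rep_evaluation <- function(object, type = c("pit", "intervals"),
                                    bins = 10, ...) {
  type <- match.arg(type)
  f <- object$forecasts
  f$method <- factor(f$method, levels = unique(f$method))
  if (type == "pit") {
    labs <- object$summary |>
      dplyr::mutate(label = sprintf("KS p = %.2g", .data$ks_p))
    ggplot2::ggplot(f, ggplot2::aes(x = .data$pit)) +
      ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
                              fill = "grey70", colour = "grey30") +
      ggplot2::geom_hline(yintercept = object$meta$n / bins,
                          linetype = "dashed") +
      ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$label),
                         x = 0.98, y = Inf, hjust = 1, vjust = 1.5,
                         inherit.aes = FALSE, size = 3) +
      ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
      ggplot2::labs(x = "PIT value", y = "Count") +
      ggplot2::theme_bw()
  } else {
    f <- f |>
      dplyr::mutate(rr = tanh(.data$theta_r),
                    lo = tanh(.data$lower), hi = tanh(.data$upper),
                    significant = .data$sig == 1)
    ggplot2::ggplot(f, ggplot2::aes(x = tanh(.data$pred_mean))) +
      ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                              colour = "grey60") +
      ggplot2::geom_point(ggplot2::aes(y = .data$rr,
                                       colour = .data$significant),
                          size = 1) +
      ggplot2::geom_abline(linetype = "dashed") +
      ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
      ggplot2::labs(x = "Predictive mean (correlation scale)",
                    y = "Replication effect estimate",
                    colour = "Significant") +
      ggplot2::theme_bw()
  }
}

#' Plot mean scores over the heterogeneity grid
#'
#' @param object A [tau_sensitivity()] result.
#' @param ... Unused.
#' @return A ggplot object with one panel per score type, the per-prior
#'   score-minimizing `tau` marked by a cross.
#' @export
autoplot.rep_tau_sensitivity <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("qs", "ls", "crps"),
                              names_to = "score", values_to = "mean_score")
  argmin <- attr(object, "argmin")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$mean_score,
                                     colour = .data$prior)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = argmin,
                        ggplot2::aes(x = .data$tau_min, y = .data$min_score),
                        shape = 4, size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$score), scales = "free_y") +
    ggplot2::labs(x = expression(tau), y = "Mean score", colour = "Prior") +
    ggplot2::theme_bw()
}

#' Replication probability as a function of the original evidence
#'
#' Probability of a significant same-direction replication against the
#' original test statistic, for a set of variance ratios `c` and relative
#' heterogeneities `d`, under both priors. The sceptical-prior curves stay at
#' their floor until the original evidence exceeds the full-shrinkage
#' threshold `t_o^2 > 1 + d`.
#'
#' @param c Variance ratios to draw.
#' @param d Relative heterogeneity values to draw (panelled).
#' @param alpha Two-sided significance level.
#' @param t_o_max Upper end of the test-statistic axis.
#' @return A ggplot object.
#' @export
plot_replication_probability <- function(c = base::c(0.5, 1, 2),
                                         d = base::c(0, 1),
                                         alpha = 0.05, t_o_max = 4) {
  cs <- c
  ds <- d
  grid <- tidyr::expand_grid(
    t_o = seq(0.05, t_o_max, length.out = 200),
    c = cs, d = ds, prior = c("flat", "sceptical"))
  grid$prob <- purrr::pmap_dbl(grid, function(t_o, c, d, prior) {
    replication_probability(t_o, c, d, alpha, prior)
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t_o, y = .data$prob,
                                     colour = factor(.data$c),
                                     linetype = .data$prior)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = qnorm(1 - alpha / 2),
                        linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$d),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(t[o]), y = "Replication probability",
                  colour = "c", linetype = "Prior") +
    ggplot2::theme_bw()
}

#' Shrinkage factor as a function of the original evidence
#'
#' @param d Relative heterogeneity values, one curve each.
#' @param t_o_max Upper end of the test-statistic axis.
#' @return A ggplot object showing `s = max(1 - (1 + d)/t_o^2, 0)`.
#' @export
plot_shrinkage <- function(d = c(0, 0.5, 1, 2), t_o_max = 6) {
  ds <- d
  grid <- tidyr::expand_grid(t_o = seq(0, t_o_max, length.out = 400), d = ds)
  grid$s <- shrinkage_factor(grid$t_o, grid$d)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t_o, y = .data$s,
                                     colour = factor(.data$d))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(t[o]), y = "Shrinkage factor s",
                  colour = "d") +
    ggplot2::theme_bw()
}

#' Heterogeneity range width on the correlation scale
#'
#' Draws [delta_of_tau()] with Cohen's small/medium/large correlation anchors
#' and the package default `tau` marked — the device used to justify
#' [default_tau].
#'
#' @param tau_max Upper end of the heterogeneity axis.
#' @return A ggplot object.
#' @export
plot_delta_tau <- function(tau_max = 0.3) {
  grid <- tibble::tibble(tau = seq(0, tau_max, length.out = 300))
  grid$delta <- delta_of_tau(grid$tau)
  anchors <- tibble::tibble(name = names(cohen_effect_sizes),
                            delta = unname(cohen_effect_sizes))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$tau, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = anchors,
                        ggplot2::aes(yintercept = .data$delta),
                        linetype = "dotted") +
    ggplot2::geom_text(data = anchors,
                       ggplot2::aes(y = .data$delta, label = .data$name),
                       x = 0, hjust = 0, vjust = -0.4, size = 3) +
    ggplot2::geom_vline(xintercept = default_tau, linetype = "dashed") +
    ggplot2::labs(x = expression(tau),
                  y = expression(delta(tau))) +
    ggplot2::theme_bw()
}
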