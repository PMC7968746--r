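#' Plot evidence against model order
#'
#' Log marginal likelihood per path count with asymmetric error bars; the
#' selected order is highlighted.
#'
#' @param object An `fp_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_selection
#' @export
autoplot.fp_selection <- function(object, ...) {
  df <- tidy.fp_selection(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$M, y = .data$log_evidence)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$log_evidence - .data$err_lo,
                   ymax = .data$log_evidence + .data$err_hi),
      width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = df$M) +
    ggplot2::labs(x = "completion paths M", y = "ln P(D | M)",
                  title = sprintf("Model selection (best M = %d)",
                                  object$best_M)) +
    ggplot2::theme_minimal()
}

#' Plot a posterior fit curve over the binned data
#'
#' @param object An `fp_curve` from [posterior_curve()].
#' @param data Optional `fp_binned` sample to overlay as a histogram density.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_curve
#' @export
autoplot.fp_curve <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$std, 0),
                                      ymax = .data$mean + .data$std),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "completion time (ms)", y = "density (1/ms)") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    td <- tidy.fp_binned(data)
    td$dens <- td$count / (data$n_total * data$dt)
    p <- p + ggplot2::geom_point(data = td[td$count > 0, ],
                                 ggplot2::aes(x = .data$mid, y = .data$dens),
                                 inherit.aes = FALSE, size = 0.6,
                                 colour = "grey40")
  }
  p
}

#' Plot path summaries across conditions
#'
#' Mean completion time, CV and weight of each matched path as a function of
#' the external condition.
#'
#' @param object An `fp_condition_series` from [match_paths()].
#' @param ... Unused.
#' @return A ggplot faceted by summary.
#' @method autoplot fp_condition_series
#' @export
autoplot.fp_condition_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("condition", "path", "mean_completion",
                                "cv", "weight")],
    cols = c("mean_completion", "cv", "weight"),
    names_to = "summary", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value,
                                     colour = factor(.data$path))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~summary, scales = "free_y") +
    ggplot2::labs(colour = "path", x = "condition", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the early-time CDF decomposition behind a state-count bound
#'
#' Empirical early CDF (points), total model CDF (solid), and per-path
#' weighted CDFs (dashed) on log-log axes.
#'
#' @param object An `fp_bound` from [min_states_lower_bound()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_bound
#' @export
autoplot.fp_bound <- function(object, ...) {
  dec <- object$decomposition
  ggplot2::ggplot() +
    ggplot2::geom_point(data = dec$events,
                        ggplot2::aes(x = .data$t, y = .data$emp_p),
                        size = 0.8) +
    ggplot2::geom_line(data = dec$events,
                       ggplot2::aes(x = .data$t, y = .data$model_cdf),
                       colour = "purple") +
    ggplot2::geom_line(data = dec$paths[dec$paths$weighted_cdf > 0, ],
                       ggplot2::aes(x = .data$t, y = .data$weighted_cdf,
                                    colour = factor(.data$path)),
                       linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "completion time (ms)", y = "CDF", colour = "path",
                  title = sprintf(">= %d internal states required",
                                  object$state_bound)) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap JSD validation streams
#'
#' @param object The tibble returned by [evaluate_prediction()].
#' @return A ggplot of the three JSD distributions.
#' @export
plot_jsd_streams <- function(object) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$jsd, fill = .data$stream)) +
    ggplot2::geom_histogram(alpha = 0.5, position = "identity", bins = 30) +
    ggplot2::labs(x = "Jensen-Shannon divergence (nats)", y = "replicates") +
    ggplot2::theme_minimal()
}
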