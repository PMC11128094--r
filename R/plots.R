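# ggplot2 graphics: credible-tube overlays and marginal posteriors.

#' Plot credible tubes over the data
#'
#' Draws the posterior-median trajectory and the credible tube per
#' condition, overlaid on the replicate measurements.
#'
#' @param object An `rtf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rtf_fit <- function(object, ...) {
  tubes <- fit_tubes(object)
  pts <- bind_rows(lapply(object$results, function(r) {
    tibble(condition = attr(r$dataset, "condition_id"),
           time = r$dataset$time, measurement = r$dataset$measurement)
  }))
  level <- attr(object$results[[1]]$tube, "level")
  ggplot2::ggplot(tubes, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$condition), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median,
                                    colour = .data$condition),
                       linewidth = 0.8) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$measurement,
                                     colour = .data$condition),
                        alpha = 0.5, size = 1) +
    ggplot2::labs(x = "time", y = "observable",
                  title = sprintf("%d%% credible tubes", round(100 * level))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rtf_fit
#' @export
autoplot.credible_tube <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue4",
                       linewidth = 0.8) +
    ggplot2::labs(x = "time", y = "observable") +
    ggplot2::theme_minimal()
}

#' Marginal posterior histograms with HDI bars
#'
#' @param fit An `rtf_fit`.
#' @param parameter Parameter name (e.g. `"p0"` or `"sigma"`).
#' @param level HDI mass (default 0.95).
#' @return A ggplot object: one density per condition, restricted to and
#'   annotated with its HDI.
#' @export
plot_marginals <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "rtf_fit"))
  draws <- bind_rows(lapply(fit$results, function(r) {
    if (!parameter %in% names(r$samples$draws)) return(NULL)
    tibble(condition = attr(r$dataset, "condition_id"),
           value = r$samples$draws[[parameter]])
  }))
  if (nrow(draws) == 0L) {
    stop("parameter '", parameter, "' not found in any posterior",
         call. = FALSE)
  }
  hdis <- draws |>
    group_by(.data$condition) |>
    summarise(lower = hdi(.data$value, level)[["lower"]],
              upper = hdi(.data$value, level)[["upper"]],
              .groups = "drop")
  draws_in <- draws |>
    left_join(hdis, by = "condition") |>
    filter(.data$value >= .data$lower, .data$value <= .data$upper)
  ggplot2::ggplot(draws_in,
                  ggplot2::aes(x = .data$value, fill = .data$condition)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::geom_segment(data = hdis,
                          ggplot2::aes(x = .data$lower, xend = .data$upper,
                                       y = 0, yend = 0,
                                       colour = .data$condition),
                          linewidth = 1.5, inherit.aes = FALSE) +
    ggplot2::labs(x = parameter, y = "posterior density",
                  title = sprintf("marginal posterior of %s (%d%% HDI)",
                                  parameter, round(100 * level))) +
    ggplot2::theme_minimal()
}
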