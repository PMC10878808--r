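#' Plot a nest trace with its detection threshold and recesses
#'
#' One day (or span) of a nest temperature trace with the daily max-drop
#' threshold and shaded detected recesses, the standard diagnostic view of
#' a thermologger recording.
#'
#' @param trace Nest trace tibble (one nest).
#' @param recesses Recess tibble for the same nest (optional).
#' @param params A [detection_params()] list (for the threshold line).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, recesses = NULL, params = detection_params()) {
  thr <- trace |>
    dplyr::mutate(date = as.Date(timestamp, tz = "UTC")) |>
    dplyr::group_by(date) |>
    dplyr::mutate(threshold = max(temp) - params$delta_max_drop) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(thr, ggplot2::aes(x = timestamp)) +
    ggplot2::geom_line(ggplot2::aes(y = temp), linewidth = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = threshold), colour = "steelblue",
                       linetype = 2) +
    ggplot2::labs(x = NULL, y = "Nest temperature (°C)") +
    ggplot2::theme_minimal()
  if (!is.null(recesses) && nrow(recesses) > 0) {
    p <- p + ggplot2::geom_rect(
      data = recesses,
      ggplot2::aes(xmin = onset, xmax = end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.2)
  }
  p
}

#' Plot the recess-duration distribution with its threshold
#'
#' Histogram of log-scaled recess durations with the two modes and the
#' antimode threshold marked, the visual justification of the
#' short/extended split.
#'
#' @param durations Recess durations (minutes), or a classified recess
#'   tibble with a `duration` column.
#' @param threshold A `recess_threshold` object.
#' @return A ggplot object.
#' @export
plot_duration_distribution <- function(durations, threshold = NULL) {
  if (is.data.frame(durations)) durations <- durations$duration
  df <- tibble::tibble(duration = durations)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = duration)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Recess duration (min, log scale)", y = "Count") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p +
      ggplot2::geom_vline(xintercept = threshold$modes, colour = "purple") +
      ggplot2::geom_vline(xintercept = threshold$antimode, colour = "orange",
                          linewidth = 1)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.recess_threshold <- function(object, durations = NULL, ...) {
  if (is.null(durations)) {
    abort("supply the durations the threshold was estimated from")
  }
  plot_duration_distribution(durations, object)
}

#' Plot a Johnson-Neyman analysis
#'
#' Conditional slope of the focal predictor across the moderator range with
#' its pointwise confidence band and the unadjusted and FDR-adjusted
#' Johnson-Neyman boundaries.
#'
#' @param fit A `recess_fit` with an interaction.
#' @param jn The matching `jn_result` from [simple_slopes_jn()].
#' @param n_grid Grid resolution over the observed moderator range.
#' @return A ggplot object.
#' @export
plot_johnson_neyman <- function(fit, jn, n_grid = 200) {
  mod_raw <- fit$data_raw[[jn$moderator]]
  grid <- seq(min(mod_raw), max(mod_raw), length.out = n_grid)
  probe <- simple_slopes_jn(fit, jn$temp, jn$moderator,
                            probe_values = grid, alpha = jn$alpha)
  sl <- probe$slopes
  tc <- jn$jn$t_crit[jn$jn$adjustment == "unadjusted"]
  sl$lo <- sl$slope - tc * sl$se
  sl$hi <- sl$slope + tc * sl$se
  bounds <- stats::na.omit(c(jn$jn$lower, jn$jn$upper))
  p <- ggplot2::ggplot(sl, ggplot2::aes(x = moderator_value, y = slope)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = jn$moderator,
                  y = paste("Conditional slope of", jn$temp)) +
    ggplot2::theme_minimal()
  if (length(bounds) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = bounds, colour = "orange",
                                 linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

utils::globalVariables(c("threshold", "lo", "hi", "moderator_value", "slope"))
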