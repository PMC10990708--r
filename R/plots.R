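#' Plot a two-phase decay fit over its histogram
#'
#' Histogram bars of binned fusion-event times with the fitted two-phase
#' exponential decay (and its fast/slow components) overlaid.
#'
#' @param object A `two_phase_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.two_phase_fit <- function(object, ...) {
  d <- object$fitted
  comp <- tibble(
    bin_left = rep(d$bin_left, 2),
    value = c(object$span_fast * exp(-object$k_fast * d$bin_left),
              object$span_slow * exp(-object$k_slow * d$bin_left)),
    component = rep(c("fast", "slow"), each = nrow(d))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_left)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), width = diff(d$bin_left[1:2]),
                      fill = "grey75", just = 0) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$value, linetype = .data$component),
                       color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "black",
                       linewidth = 0.8) +
    ggplot2::labs(
      x = "time after injection (s)", y = "fusion events per bin",
      title = sprintf("two-phase decay: %.0f%% fast, k_fast = %.3g/s, R² = %.3f",
                      object$percent_fast, object$k_fast, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot example simulated traces
#'
#' @param object An `sv_simulation`.
#' @param trace_ids Which traces to show (default: first 4).
#' @param ... Unused.
#' @return A ggplot with label and content channels per trace.
#' @export
autoplot.sv_simulation <- function(object, trace_ids = NULL, ...) {
  ids <- trace_ids %||% head(unique(object$traces$trace_id), 4)
  d <- object$traces |>
    filter(.data$trace_id %in% ids) |>
    tidyr::pivot_longer(c("label_intensity", "content_intensity"),
                        names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$intensity,
                                  color = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$config$injection_time,
                        linetype = "dashed", color = "grey50") +
    ggplot2::facet_wrap(~trace_id, scales = "free_y") +
    ggplot2::scale_color_manual(values = c(label_intensity = "#c0392b",
                                           content_intensity = "#1e8449")) +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Cumulative fusion-event curves per condition
#'
#' @param event_times_by_condition Named list of post-injection event-time
#'   vectors (s).
#' @return A ggplot of right-continuous empirical CDFs.
#' @export
plot_cumulative_curves <- function(event_times_by_condition) {
  d <- imap(event_times_by_condition, function(times, cond) {
    cumulative_event_curve(times) |> mutate(condition = cond)
  }) |> list_rbind()
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$cumulative_fraction,
                                  color = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time after injection (s)",
                  y = "cumulative fraction of fusion events") +
    ggplot2::theme_minimal()
}

#' Bar plot of bootstrap synchronization means with SEM error bars
#'
#' @param bootstrap_tbl The `bootstrap` tibble from
#'   [compare_synchronization()].
#' @return A ggplot.
#' @export
plot_synchronization <- function(bootstrap_tbl) {
  stopifnot(is.data.frame(bootstrap_tbl),
            all(c("condition", "mean", "sem") %in% names(bootstrap_tbl)))
  ggplot2::ggplot(bootstrap_tbl,
                  ggplot2::aes(.data$condition, 100 * .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * (.data$mean - .data$sem),
                                        ymax = 100 * (.data$mean + .data$sem)),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "fusion in first second (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
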