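#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a two-phase decay fit
#'
#' @param x A `two_phase_fit`.
#' @param ... Unused.
#' @return One row per model component (fast/slow): `component`, `span`,
#'   `rate_per_s`, `percent_of_span`.
#' @export
tidy.two_phase_fit <- function(x, ...) {
  tibble(
    component = c("fast", "slow"),
    span = c(x$span_fast, x$span_slow),
    rate_per_s = c(x$k_fast, x$k_slow),
    percent_of_span = c(x$percent_fast, 100 - x$percent_fast)
  )
}

#' @rdname tidy.two_phase_fit
#' @return `glance()`: one-row fit summary (`percent_fast`, `k_fast`,
#'   `k_slow`, `r_squared`, `sse`, `n_bins`, `n_events`, `unreliable`).
#' @export
glance.two_phase_fit <- function(x, ...) {
  tibble(
    percent_fast = x$percent_fast, k_fast = x$k_fast, k_slow = x$k_slow,
    r_squared = x$r_squared, sse = x$sse, n_bins = x$n_bins,
    n_events = x$n_events, unreliable = x$unreliable
  )
}

#' Tidy a bootstrap-subset result
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per subset (`subset`, `statistic`); `glance()`:
#'   one-row summary (`mean`, `sd`, `sem`, `n_subsets`, `subset_size`,
#'   `replacement`).
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble(subset = seq_along(x$subset_statistics),
         statistic = x$subset_statistics)
}

#' @rdname tidy.bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, sem = x$sem, n_subsets = x$n_subsets,
         subset_size = x$subset_size, replacement = x$replacement)
}

#' Tidy a diameter summary
#'
#' @param x A `diameter_summary`.
#' @param ... Unused.
#' @return `tidy()`: the histogram tibble; `glance()`: one-row summary.
#' @export
tidy.diameter_summary <- function(x, ...) x$histogram

#' @rdname tidy.diameter_summary
#' @export
glance.diameter_summary <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, sd = x$sd, sem = x$sem,
         geometric_mean = x$geometric_mean,
         geometric_sd_factor = x$geometric_sd_factor)
}
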