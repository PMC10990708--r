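#' Parameter-recovery study for the two-phase decay fitter
#'
#' Simulates Poisson-noised event-count histograms from the span-model
#' two-phase decay at a given condition's percent-fast and rates, fits each
#' replicate with [fit_two_phase_decay()], and returns the recovered
#' parameters per seed. Span amplitudes are scaled so the total expected
#' count over the window is `total_events` (identifiability at realistic
#' event numbers), keeping the requested span shares: with printed percent
#' pairs that do not sum to exactly 100 the shares are normalized to their
#' sum.
#'
#' @param percent_fast,percent_slow Printed span percentages of the fast and
#'   slow components (`percent_slow` defaults to `100 - percent_fast`).
#' @param k_fast,k_slow Generating decay rates (s^-1), `k_fast >= k_slow`.
#' @param total_events Total expected histogram count over the window.
#' @param bin_width,window Histogram geometry in seconds.
#' @param seeds Integer vector; one simulated replicate per seed.
#' @return Tibble with one row per seed: recovered `k_fast`, `k_slow`,
#'   `percent_fast`, `r_squared`, plus the generating `span_fast`/`span_slow`.
#' @export
#' @examples
#' \donttest{
#' study <- decay_recovery_study(70, k_fast = 0.3, k_slow = 0.001, seeds = 1:5)
#' median(study$k_fast)
#' }
decay_recovery_study <- function(percent_fast, k_fast, k_slow,
                                 percent_slow = 100 - percent_fast,
                                 total_events = 500, bin_width = 0.2,
                                 window = 53, seeds = 1:20) {
  check_rate_order(k_fast, k_slow)
  stopifnot(percent_fast >= 0, percent_slow >= 0,
            percent_fast + percent_slow > 0)
  share_fast <- percent_fast / (percent_fast + percent_slow)
  tt <- seq(0, window - bin_width, by = bin_width)
  sum_fast <- sum(exp(-k_fast * tt))
  sum_slow <- sum(exp(-k_slow * tt))
  scale <- total_events / (share_fast * sum_fast + (1 - share_fast) * sum_slow)
  span_fast <- share_fast * scale
  span_slow <- (1 - share_fast) * scale
  edges <- c(tt, window)

  map(seeds, function(s) {
    h <- simulate_histogram_counts(span_fast, span_slow, k_fast, k_slow,
                                   bin_edges = edges, seed = s)
    fit <- fit_two_phase_decay(h)
    tibble(seed = s, k_fast = fit$k_fast, k_slow = fit$k_slow,
           percent_fast = fit$percent_fast, r_squared = fit$r_squared,
           span_fast = span_fast, span_slow = span_slow)
  }) |> list_rbind()
}
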