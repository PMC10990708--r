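#' Fraction of values at or below a cutoff
#'
#' The per-subset statistic used for fusion synchronization: the fraction of
#' event times falling in `[0, window_s]`.
#'
#' @param x Numeric vector.
#' @param window_s Cutoff in seconds.
#' @return A single fraction in \[0, 1\].
#' @export
fraction_within <- function(x, window_s = 1) {
  sum(x >= 0 & x <= window_s) / length(x)
}

#' Bootstrap-subset summary of a statistic
#'
#' Draws `n_subsets` random subsets of `subset_size` items from a population
#' (with or without replacement), evaluates `statistic` on each subset, and
#' summarizes the subset statistics by their mean, SD and SEM
#' (`SD / sqrt(n_subsets)`). This is the subset-resampling scheme used to
#' attach an uncertainty to the fusion-synchronization fraction when the
#' per-experiment event counts are too small for replicate-level statistics:
#' the "data items" are individual fusion-event times and the per-subset
#' statistic is the subset's first-second fraction.
#'
#' @param population Non-empty numeric vector (e.g. fusion-event times, s).
#' @param statistic Function mapping a numeric vector to a single number.
#'   Defaults to [fraction_within()] with a 1 s window.
#' @param subset_size Items per subset (<= population size when
#'   `replacement = FALSE`).
#' @param n_subsets Number of subsets (default 10).
#' @param replacement Draw subsets with replacement? Default `FALSE`.
#' @param seed Integer seed; subsets are drawn independently of each other.
#' @return A `bootstrap_result` list: `subset_statistics`, `mean`, `sd`,
#'   `sem`, `n_subsets`, `subset_size`, `replacement`, `seed`. Supports
#'   [tidy()][generics::tidy] and [glance()][generics::glance].
#' @export
#' @examples
#' bootstrap_statistic(c(0.2, 0.4, 3, 8, 12), subset_size = 3, seed = 1)
bootstrap_statistic <- function(population,
                                statistic = function(x) fraction_within(x, 1),
                                subset_size, n_subsets = 10,
                                replacement = FALSE, seed = 1L) {
  if (length(population) == 0L || !is.numeric(population)) {
    abort("`population` must be a non-empty numeric vector.",
          class = "svfusion_input_error")
  }
  subset_size <- check_count(subset_size, "subset_size")
  n_subsets <- check_count(n_subsets, "n_subsets")
  if (!replacement && subset_size > length(population)) {
    abort("`subset_size` exceeds the population for sampling without replacement.",
          class = "svfusion_parameter_error")
  }
  stats_vec <- with_seed(seed, {
    vapply(seq_len(n_subsets), function(i) {
      idx <- sample.int(length(population), subset_size, replace = replacement)
      as.numeric(statistic(population[idx]))
    }, numeric(1))
  })
  s <- sd(stats_vec)
  structure(
    list(
      subset_statistics = stats_vec,
      mean = mean(stats_vec),
      sd = s,
      sem = s / sqrt(n_subsets),
      n_subsets = n_subsets,
      subset_size = subset_size,
      replacement = replacement,
      seed = as.integer(seed)
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> mean %.4g, SD %.4g, SEM %.4g (%d subsets of %d, %s replacement)\n",
    x$mean, x$sd, x$sem, x$n_subsets, x$subset_size,
    if (x$replacement) "with" else "without"))
  invisible(x)
}

#' Unpaired two-tailed Student's t-test
#'
#' Equal-variance (pooled) two-sample t-test with `df = n_a + n_b - 2`, the
#' comparison used for synchronization and association-class contrasts.
#' Degenerate inputs follow two conventions: zero pooled variance with equal
#' means gives `t = 0, p = 1`; zero pooled variance with unequal means is an
#' error (the statistic is undefined). Welch's unequal-variance test is
#' available via `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (Student's test)? Default `TRUE`.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' two_sample_ttest(rnorm(10), rnorm(10))
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("both samples need at least 2 values.",
          class = "svfusion_input_error")
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2L, p_value = 1,
                    mean_a = mean(a), mean_b = mean(b)))
    }
    abort("zero variance in both samples with unequal means: t is undefined.",
          class = "svfusion_degenerate_input")
  }
  ht <- t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' All pairwise synchronization comparisons between conditions
#'
#' Runs [bootstrap_statistic()] per condition and an unpaired two-tailed
#' Student's t-test on the subset statistics of every condition pair. No
#' multiple-testing correction is applied (the pairwise tests are reported
#' raw, as is conventional for this assay's small condition panels).
#'
#' @param event_times_by_condition Named list of numeric event-time vectors.
#' @param subset_sizes Named integer vector of subset sizes per condition
#'   (recycled from a single value).
#' @param n_subsets,replacement,seed Passed to [bootstrap_statistic()]; each
#'   condition gets a distinct seed derived from `seed`.
#' @param window_s Synchronization window (s).
#' @return List with `bootstrap` (tibble: condition, mean, sd, sem) and
#'   `comparisons` (tibble: condition_a, condition_b, t, df, p_value).
#' @export
compare_synchronization <- function(event_times_by_condition, subset_sizes,
                                    n_subsets = 10, replacement = FALSE,
                                    seed = 1L, window_s = 1) {
  stopifnot(is.list(event_times_by_condition),
            !is.null(names(event_times_by_condition)))
  conds <- names(event_times_by_condition)
  if (length(subset_sizes) == 1L) {
    subset_sizes <- setNames(rep(subset_sizes, length(conds)), conds)
  }
  boots <- imap(event_times_by_condition, function(times, cond) {
    bootstrap_statistic(
      times,
      statistic = function(x) fraction_within(x, window_s),
      subset_size = subset_sizes[[cond]],
      n_subsets = n_subsets, replacement = replacement,
      seed = seed + match(cond, conds)
    )
  })
  summary_tbl <- imap(boots, function(b, cond) {
    tibble(condition = cond, mean = b$mean, sd = b$sd, sem = b$sem,
           n_subsets = b$n_subsets, subset_size = b$subset_size)
  }) |> list_rbind()
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  comparisons <- map(pairs, function(p) {
    tt <- two_sample_ttest(boots[[p[1]]]$subset_statistics,
                           boots[[p[2]]]$subset_statistics)
    tibble(condition_a = p[1], condition_b = p[2],
           t = tt$t, df = tt$df, p_value = tt$p_value)
  }) |> list_rbind()
  list(bootstrap = summary_tbl, comparisons = comparisons)
}
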