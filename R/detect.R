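#' Detect steps in a fluorescence intensity series
#'
#' Fits a piecewise-constant model by exact penalized least-squares
#' partitioning (optimal-partitioning dynamic program, penalty
#' `2 * sigma^2 * log(n)` with sigma estimated by [estimate_noise_sigma()]),
#' then reports the level changes between consecutive segments. Steps smaller
#' than `min_step_sigma` baseline sigmas are discarded; with `merge_pruned =
#' TRUE` (default) each discarded step re-merges its flanking segments so the
#' surviving amplitudes stay consistent — the right semantics for staircase
#' signals such as stepwise association. For transient rise-then-decay pulses
#' (the content-channel fusion signature) merging is destructive, because
#' absorbing sub-threshold decay steps drags the post-rise level back toward
#' baseline until the rise itself is erased; `merge_pruned = FALSE` instead
#' keeps the raw between-segment amplitudes and simply omits the small ones.
#'
#' @param signal Numeric intensity series, length >= 10.
#' @param frame_interval Seconds per frame (used only to report `time_s`).
#' @param min_step_sigma Minimum reportable step magnitude in noise sigmas.
#' @param merge_pruned Re-merge segments around discarded sub-threshold steps.
#' @return Tibble with one row per step: `frame` (first frame of the new
#'   level), `time_s`, `amplitude` (signed level change, a.u.), `sign`
#'   (`"+"`/`"-"`), sorted by frame. Zero rows if no step survives.
#' @export
#' @examples
#' x <- c(rep(0, 50), rep(10, 50)) + rnorm(100, sd = 1)
#' detect_steps(x, frame_interval = 0.2, min_step_sigma = 4)
detect_steps <- function(signal, frame_interval = 0.2, min_step_sigma = 4,
                         merge_pruned = TRUE) {
  if (!is.numeric(signal) || length(signal) < 10L) {
    abort("`signal` must be a numeric series of length >= 10.",
          class = "svfusion_input_error")
  }
  n <- length(signal)
  sigma <- estimate_noise_sigma(signal)
  scale <- max(diff(range(signal)), 1e-12)
  # noiseless input: a vanishing penalty still disfavours spurious splits
  # (splitting a constant segment saves exactly zero cost)
  penalty <- if (sigma > 0) 2 * sigma^2 * log(n) else 1e-10 * scale^2
  bounds <- optimal_partition(signal, penalty)
  threshold <- min_step_sigma * sigma
  steps <- prune_small_steps(signal, bounds, threshold, merge = merge_pruned)
  tibble(
    frame = steps$frame,
    time_s = (steps$frame - 1) * frame_interval,
    amplitude = steps$amplitude,
    sign = ifelse(steps$amplitude >= 0, "+", "-")
  )
}

# Exact optimal partitioning under squared-error segment cost + per-segment
# penalty. Returns the last frame index of each non-final segment (so the
# signal level changes at index + 1). O(n^2), vectorized inner loop.
optimal_partition <- function(x, penalty) {
  n <- length(x)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  f <- c(-penalty, rep(Inf, n))
  prev <- integer(n + 1L)
  for (t in seq_len(n)) {
    s <- 0:(t - 1L)
    cost <- (s2[t + 1L] - s2[s + 1L]) - (s1[t + 1L] - s1[s + 1L])^2 / (t - s)
    vals <- f[s + 1L] + cost + penalty
    j <- which.min(vals)
    f[t + 1L] <- vals[j]
    prev[t + 1L] <- s[j]
  }
  bounds <- integer(0)
  t <- n
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) bounds <- c(s, bounds)
    t <- s
  }
  bounds
}

# Drop steps below threshold; `merge` re-merges segments each time (smallest
# step first), otherwise the raw between-segment amplitudes are filtered.
prune_small_steps <- function(x, bounds, threshold, merge = TRUE) {
  repeat {
    edges <- c(0L, bounds, length(x))
    means <- vapply(seq_len(length(edges) - 1L), function(i) {
      mean(x[(edges[i] + 1L):edges[i + 1L]])
    }, numeric(1))
    amps <- diff(means)
    if (length(amps) == 0L) {
      return(list(frame = integer(0), amplitude = numeric(0)))
    }
    small <- which(abs(amps) < threshold)
    if (length(small) == 0L) {
      return(list(frame = bounds + 1L, amplitude = amps))
    }
    if (!merge) {
      keep <- setdiff(seq_along(amps), small)
      return(list(frame = bounds[keep] + 1L, amplitude = amps[keep]))
    }
    drop <- small[which.min(abs(amps[small]))]
    bounds <- bounds[-drop]
  }
}

#' Detect the arrival of the injected solution in the label channel
#'
#' The co-injected free dye raises the label channel of every trace; injection
#' arrival is the first frame whose label intensity exceeds the baseline mean
#' by at least `threshold_sigma` baseline sigmas and stays elevated for at
#' least 3 consecutive frames.
#'
#' @param trace Single-trace tibble with columns `time_s` and
#'   `label_intensity` (e.g. one trace of [simulate_traces()] output).
#' @param n_baseline_frames Frames used to estimate the baseline level and
#'   noise sigma.
#' @param threshold_sigma Detection threshold in baseline sigmas.
#' @return One-row tibble: `detected` (logical), `frame`, `time_s`, `score`
#'   (step contrast in sigmas). `frame`/`time_s`/`score` are `NA` when no
#'   injection is detected.
#' @export
detect_injection <- function(trace, n_baseline_frames = 30,
                             threshold_sigma = 5) {
  stopifnot(is.data.frame(trace), all(c("time_s", "label_intensity") %in%
                                        names(trace)))
  x <- trace$label_intensity
  nb <- check_count(n_baseline_frames, "n_baseline_frames", min = 2L)
  if (length(x) <= nb) {
    abort("trace shorter than the baseline window.",
          class = "svfusion_input_error")
  }
  mu <- mean(x[seq_len(nb)])
  sigma <- estimate_noise_sigma(x[seq_len(nb)])
  if (sigma == 0 && all(x == mu)) {
    abort("noise sigma not estimable from a constant trace.",
          class = "svfusion_estimation_error")
  }
  elevated <- x > mu + threshold_sigma * sigma
  # first frame of a run of >= 3 elevated frames
  run <- elevated & c(elevated[-1], FALSE) & c(elevated[-(1:2)], FALSE, FALSE)
  hit <- which(run)
  hit <- hit[hit > nb]
  if (length(hit) == 0L) {
    return(tibble(detected = FALSE, frame = NA_integer_, time_s = NA_real_,
                  score = NA_real_))
  }
  f <- hit[1]
  level <- mean(x[f:min(f + 2L, length(x))])
  score <- if (sigma > 0) (level - mu) / sigma else Inf
  tibble(detected = TRUE, frame = as.integer(f), time_s = trace$time_s[f],
         score = score)
}

#' Classify an association event from label-channel steps
#'
#' Counts the positive label-channel steps of a trace, excluding any step
#' within 2 frames of the detected injection (the free-dye step is a global
#' background rise, not a vesicle docking). One positive step is a single
#' association; two or more are a multiple association. Negative steps
#' (departures) never decrement the count.
#'
#' @param steps Step tibble from [detect_steps()] on the label channel.
#' @param injection Optional one-row tibble from [detect_injection()].
#' @return One-row tibble (`first_step_frame`, `n_steps`, `class`), or `NULL`
#'   when no positive association step remains.
#' @export
classify_association <- function(steps, injection = NULL) {
  stopifnot(is.data.frame(steps))
  if (!is.null(injection) && isTRUE(injection$detected[1])) {
    steps <- steps[abs(steps$frame - injection$frame[1]) > 2L, , drop = FALSE]
  }
  pos <- steps[steps$amplitude > 0, , drop = FALSE]
  if (nrow(pos) == 0L) return(NULL)
  tibble(
    first_step_frame = as.integer(min(pos$frame)),
    n_steps = nrow(pos),
    class = if (nrow(pos) > 1L) "multiple" else "single"
  )
}

#' Detect a content-mixing fusion event in the content channel
#'
#' A fusion is the first positive content-channel step of at least
#' `min_rise_sigma` noise sigmas (sulforhodamine B dequenching) that is
#' followed by a decaying trend — a negative least-squares slope over the
#' subsequent frames (at least 5 required). Event time is reported relative
#' to the injection when one is supplied; events before injection, or in
#' traces with no injection, are cation-independent.
#'
#' @param trace Single-trace tibble with `time_s` and `content_intensity`.
#' @param injection Optional one-row tibble from [detect_injection()].
#' @param min_rise_sigma Minimum rise amplitude in content-channel sigmas.
#' @param decay_window_frames Frames after the rise used to assess the decay
#'   trend (capped at the next detected step and the trace end).
#' @return One-row tibble (`fusion_frame`, `time_s`,
#'   `time_after_injection_s`, `category`), or `NULL` when no fusion is found.
#' @export
detect_fusion <- function(trace, injection = NULL, min_rise_sigma = 4,
                          decay_window_frames = 10) {
  stopifnot(is.data.frame(trace), all(c("time_s", "content_intensity") %in%
                                        names(trace)))
  x <- trace$content_intensity
  t_s <- trace$time_s
  dt <- stats::median(diff(t_s))
  steps <- detect_steps(x, frame_interval = dt, min_step_sigma = min_rise_sigma,
                        merge_pruned = FALSE)
  rises <- steps[steps$amplitude > 0, , drop = FALSE]
  if (nrow(rises) == 0L) return(NULL)
  # the decay itself produces negative steps in the piecewise-constant fit;
  # only a later positive step (another rise) truncates the decay window
  boundaries <- c(rises$frame, length(x) + 1L)
  for (i in seq_len(nrow(rises))) {
    f <- rises$frame[i]
    lim <- min(boundaries[boundaries > f] - 1L, f + decay_window_frames,
               length(x))
    if (lim - f < 5L) next  # not enough frames to verify the decay
    idx <- f:lim
    slope <- coef(lm(x[idx] ~ t_s[idx]))[2]
    if (is.finite(slope) && slope < 0) {
      inj_ok <- !is.null(injection) && isTRUE(injection$detected[1])
      t_after <- if (inj_ok) t_s[f] - injection$time_s[1] else NA_real_
      category <- if (!inj_ok || t_after < 0) {
        "cation_independent"
      } else if (t_after <= 1) "immediate" else "delayed"
      return(tibble(fusion_frame = as.integer(f), time_s = t_s[f],
                    time_after_injection_s = t_after, category = category))
    }
  }
  NULL
}

#' Dwell time between association and fusion
#'
#' Time between formation of an associated vesicle pair (its first label-step
#' frame) and fusion.
#'
#' @param association One-row tibble from [classify_association()].
#' @param fusion One-row tibble from [detect_fusion()].
#' @param frame_interval Seconds per frame.
#' @return Dwell time in seconds (0 for fusion at the association frame).
#' @export
#' @examples
#' a <- tibble::tibble(first_step_frame = 10L)
#' f <- tibble::tibble(fusion_frame = 128L)
#' dwell_time(a, f, frame_interval = 0.2) # 23.6 s
dwell_time <- function(association, fusion, frame_interval) {
  stopifnot(is.data.frame(association), is.data.frame(fusion))
  check_positive_rate(frame_interval, "frame_interval")
  d <- fusion$fusion_frame[1] - association$first_step_frame[1]
  if (d < 0) {
    abort("fusion precedes the first association step.",
          class = "svfusion_ordering_error")
  }
  d * frame_interval
}

#' Run event detection over a set of traces
#'
#' Applies injection, association-step and fusion detection to every trace of
#' a long-format trace table. The injection frame is located on the median
#' label-intensity series across traces (the free-dye step is common to all
#' traces while association steps are not), then each trace is analyzed
#' against that mark.
#'
#' The free-dye offset is by design the largest label-channel step of the
#' median trace (per-trace association steps average out across traces, and
#' each contributes at most its own step height to the median), so the
#' injection mark is taken at the largest positive step of the median series;
#' if the median series carries no detectable step, the baseline-threshold
#' rule of [detect_injection()] is used as fallback.
#'
#' @param traces Long tibble with columns `trace_id`, `frame`, `time_s`,
#'   `label_intensity`, `content_intensity`.
#' @param n_baseline_frames,threshold_sigma Passed to [detect_injection()]
#'   for the fallback injection search.
#' @param min_step_sigma Passed to [detect_steps()] (label channel).
#' @param min_rise_sigma Passed to [detect_fusion()] (content channel).
#' @return Tibble with one row per trace: association class and step count,
#'   fusion frame/category, fusion time relative to injection, and dwell
#'   time. The detected injection mark is attached as attribute `injection`.
#' @export
detect_events <- function(traces, n_baseline_frames = 30, threshold_sigma = 5,
                          min_step_sigma = 4, min_rise_sigma = 4) {
  stopifnot(is.data.frame(traces),
            all(c("trace_id", "frame", "time_s", "label_intensity",
                  "content_intensity") %in% names(traces)))
  median_trace <- traces |>
    group_by(.data$frame) |>
    summarise(time_s = .data$time_s[1],
              label_intensity = stats::median(.data$label_intensity),
              .groups = "drop")
  dt <- stats::median(diff(median_trace$time_s))
  med_steps <- detect_steps(median_trace$label_intensity, frame_interval = dt,
                            min_step_sigma = min_step_sigma)
  med_pos <- med_steps[med_steps$amplitude > 0, , drop = FALSE]
  injection <- if (nrow(med_pos) > 0L) {
    j <- which.max(med_pos$amplitude)
    sig <- max(estimate_noise_sigma(median_trace$label_intensity), 1e-12)
    tibble(detected = TRUE, frame = med_pos$frame[j],
           time_s = median_trace$time_s[med_pos$frame[j]],
           score = med_pos$amplitude[j] / sig)
  } else {
    detect_injection(median_trace, n_baseline_frames, threshold_sigma)
  }

  out <- traces |>
    dplyr::group_split(.data$trace_id) |>
    map(function(tr) {
      steps <- detect_steps(tr$label_intensity, frame_interval = dt,
                            min_step_sigma = min_step_sigma)
      assoc <- classify_association(steps, injection)
      fusion <- detect_fusion(tr, injection, min_rise_sigma = min_rise_sigma)
      dwell <- if (!is.null(assoc) && !is.null(fusion) &&
                   fusion$fusion_frame[1] >= assoc$first_step_frame[1]) {
        dwell_time(assoc, fusion, dt)
      } else NA_real_
      tibble(
        trace_id = tr$trace_id[1],
        associated = !is.null(assoc),
        n_steps = if (is.null(assoc)) 0L else assoc$n_steps,
        class = if (is.null(assoc)) NA_character_ else assoc$class,
        first_step_frame = if (is.null(assoc)) NA_integer_ else
          assoc$first_step_frame,
        fused = !is.null(fusion),
        fusion_frame = if (is.null(fusion)) NA_integer_ else
          fusion$fusion_frame,
        fusion_time_s = if (is.null(fusion)) NA_real_ else
          fusion$time_after_injection_s,
        fusion_category = if (is.null(fusion)) NA_character_ else
          fusion$category,
        dwell_time_s = dwell
      )
    }) |>
    list_rbind()
  attr(out, "injection") <- injection
  out
}
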