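#' Simulation configuration for synthetic two-channel fusion-assay traces
#'
#' Bundles and validates every knob of the trace generator. Defaults mirror
#' the acquisition design the analysis assumes: 0.2 s frames (5 frames = 1 s),
#' a 30-frame baseline, cation injection arriving at 7 s marked by a free-dye
#' step in the label channel, and a 60 s acquisition window.
#'
#' @param frame_interval Seconds per frame. Default 0.2 s.
#' @param n_baseline_frames Baseline frames recorded before anything happens.
#' @param injection_time Injection arrival time in seconds from acquisition
#'   start. Must fall inside the acquisition window.
#' @param acquisition_duration Total acquisition length in seconds.
#' @param noise_sigma Additive Gaussian camera noise sigma (a.u.).
#' @param label_baseline,content_baseline Baseline intensities (a.u.) of the
#'   vesicle-label (Alexa-647) and content-dye (sulforhodamine B) channels.
#' @param association_step_amplitude Label-channel step height per docking
#'   vesicle, in a.u.; with `noise_sigma = 1` this is the step SNR in sigmas.
#' @param free_dye_offset Label-channel step at injection caused by co-injected
#'   free dye (a.u.).
#' @param content_rise_amplitude Content-channel dequenching rise at fusion
#'   (a.u.).
#' @param content_decay_rate Exponential decay rate (s^-1) of the content
#'   signal after the fusion rise.
#' @param fraction_fast,k_fast,k_slow Two-phase exponential mixture governing
#'   post-injection fusion latencies: a latency is drawn from the fast
#'   exponential (rate `k_fast`, s^-1) with probability `fraction_fast`, else
#'   from the slow one (`k_slow`). Requires `k_fast >= k_slow > 0`.
#' @param fraction_multiple_association Fraction of traces carrying two or
#'   more association steps.
#' @param p_spontaneous_fusion Probability that an associated trace fuses
#'   before injection (cation-independent fusion).
#' @param p_fusion Probability that an associated trace (not already fused
#'   spontaneously) fuses after injection.
#' @param n_traces Number of traces to generate.
#' @param seed Integer RNG seed; fixes every random draw.
#' @return A validated `sim_config` list.
#' @seealso [simulate_traces()]
#' @export
#' @examples
#' cfg <- sim_config(n_traces = 10, seed = 1)
#' cfg$frame_interval
sim_config <- function(frame_interval = 0.2,
                       n_baseline_frames = 30,
                       injection_time = 7,
                       acquisition_duration = 60,
                       noise_sigma = 1,
                       label_baseline = 20,
                       content_baseline = 10,
                       association_step_amplitude = 6,
                       free_dye_offset = 10,
                       content_rise_amplitude = 8,
                       content_decay_rate = 0.5,
                       fraction_fast = 0.7,
                       k_fast = 0.3,
                       k_slow = 0.001,
                       fraction_multiple_association = 0.05,
                       p_spontaneous_fusion = 0.01,
                       p_fusion = 0.5,
                       n_traces = 100,
                       seed = 1L) {
  check_positive_rate(frame_interval, "frame_interval")
  check_count(n_baseline_frames, "n_baseline_frames", min = 2L)
  check_positive_rate(acquisition_duration, "acquisition_duration")
  check_rate_order(k_fast, k_slow)
  check_positive_rate(content_decay_rate, "content_decay_rate")
  check_fraction(fraction_fast, "fraction_fast")
  check_fraction(fraction_multiple_association, "fraction_multiple_association")
  check_fraction(p_spontaneous_fusion, "p_spontaneous_fusion")
  check_fraction(p_fusion, "p_fusion")
  check_count(n_traces, "n_traces")
  check_count(seed, "seed", min = -.Machine$integer.max)
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.", class = "svfusion_parameter_error")
  }
  n_frames <- round(acquisition_duration / frame_interval)
  injection_frame <- round(injection_time / frame_interval) + 1L
  if (injection_frame < 1L || injection_frame > n_frames) {
    abort("`injection_time` must lie inside the acquisition window.",
          class = "svfusion_parameter_error")
  }
  structure(
    list(
      frame_interval = frame_interval,
      n_baseline_frames = as.integer(n_baseline_frames),
      injection_time = injection_time,
      acquisition_duration = acquisition_duration,
      noise_sigma = noise_sigma,
      label_baseline = label_baseline,
      content_baseline = content_baseline,
      association_step_amplitude = association_step_amplitude,
      free_dye_offset = free_dye_offset,
      content_rise_amplitude = content_rise_amplitude,
      content_decay_rate = content_decay_rate,
      fraction_fast = fraction_fast,
      k_fast = k_fast,
      k_slow = k_slow,
      fraction_multiple_association = fraction_multiple_association,
      p_spontaneous_fusion = p_spontaneous_fusion,
      p_fusion = p_fusion,
      n_traces = as.integer(n_traces),
      seed = as.integer(seed),
      n_frames = as.integer(n_frames),
      injection_frame = injection_frame
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_traces, " traces, ", x$n_frames, " frames @ ",
      x$frame_interval, " s; injection at ", x$injection_time, " s (frame ",
      x$injection_frame, "); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# mixture sampler on the ambient RNG; window truncation by rejection
sample_event_times_impl <- function(fraction_fast, k_fast, k_slow, n, window) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    fast <- runif(m) < fraction_fast
    t <- ifelse(fast, rexp(m, rate = k_fast), rexp(m, rate = k_slow))
    out <- c(out, t[t <= window])
  }
  out[seq_len(n)]
}

#' Draw fusion-event latencies from a two-phase exponential mixture
#'
#' Each latency comes from the fast exponential (rate `k_fast`) with
#' probability `fraction_fast` and from the slow exponential (`k_slow`)
#' otherwise. Draws falling outside `[0, window]` are rejected and redrawn, so
#' the returned sample follows the window-truncated mixture exactly.
#'
#' @param fraction_fast Mixture weight of the fast component, in \[0, 1\].
#' @param k_fast,k_slow Component rates (s^-1), `k_fast >= k_slow > 0`.
#' @param n Number of latencies to draw.
#' @param window Truncation window (s), > 0.
#' @param seed Integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @return Numeric vector of `n` event times in `[0, window]`.
#' @export
#' @examples
#' t <- sample_event_times(0.7, k_fast = 0.3, k_slow = 0.001,
#'                         n = 1000, window = 53, seed = 1)
#' mean(t <= 1) # share of first-second events
sample_event_times <- function(fraction_fast, k_fast, k_slow, n, window,
                               seed = 1L) {
  check_fraction(fraction_fast, "fraction_fast")
  check_rate_order(k_fast, k_slow)
  check_count(n, "n")
  check_positive_rate(window, "window")
  with_seed(seed,
            sample_event_times_impl(fraction_fast, k_fast, k_slow, n, window))
}

#' Simulate Poisson histogram counts from the two-phase span-model decay
#'
#' Generates per-bin event counts as independent Poisson draws whose means
#' follow `span_fast * exp(-k_fast * t) + span_slow * exp(-k_slow * t)`. By
#' default the mean is evaluated at each bin's left edge, matching how a decay
#' curve is conventionally fit to histogram bar heights; `bin_integrated =
#' TRUE` instead uses the bin-averaged model (integral over the bin divided by
#' its width).
#'
#' @param span_fast,span_slow Component amplitudes (expected counts/bin at
#'   t = 0), >= 0.
#' @param k_fast,k_slow Decay rates (s^-1), `k_fast >= k_slow > 0`.
#' @param bin_edges Strictly increasing bin edges (s).
#' @param seed Integer seed.
#' @param bin_integrated Use the bin-averaged model mean instead of the
#'   left-edge convention.
#' @return Tibble with columns `bin_left`, `bin_right`, `model_mean`, `count`.
#' @export
#' @examples
#' simulate_histogram_counts(70, 30, 0.3, 0.001,
#'                           bin_edges = seq(0, 5, 0.2), seed = 1)
simulate_histogram_counts <- function(span_fast, span_slow, k_fast, k_slow,
                                      bin_edges, seed = 1L,
                                      bin_integrated = FALSE) {
  if (!is.numeric(span_fast) || !is.numeric(span_slow) ||
      span_fast < 0 || span_slow < 0) {
    abort("spans must be >= 0.", class = "svfusion_parameter_error")
  }
  check_rate_order(k_fast, k_slow)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    abort("`bin_edges` must be strictly increasing with >= 2 edges.",
          class = "svfusion_parameter_error")
  }
  left <- bin_edges[-length(bin_edges)]
  right <- bin_edges[-1]
  mu <- if (bin_integrated) {
    # closed-form bin average of each exponential component
    (span_fast * (exp(-k_fast * left) - exp(-k_fast * right)) / k_fast +
       span_slow * (exp(-k_slow * left) - exp(-k_slow * right)) / k_slow) /
      (right - left)
  } else {
    span_fast * exp(-k_fast * left) + span_slow * exp(-k_slow * left)
  }
  counts <- with_seed(seed, rpois(length(mu), lambda = mu))
  tibble(bin_left = left, bin_right = right, model_mean = mu,
         count = as.integer(counts))
}

#' Simulate ground-truthed two-channel fusion-assay traces
#'
#' Generates `config$n_traces` synthetic traces of the label (Alexa-647) and
#' content (sulforhodamine B) channels together with the exact ground truth
#' of every planted event. Each trace carries one or more stepwise label
#' increases (vesicle associations) before injection; the free-dye step raises
#' the label channel of every trace at the injection frame; fusing traces show
#' a content-channel rise at the fusion frame followed by exponential decay.
#' Post-injection fusion latencies follow the two-phase exponential mixture; a
#' small fraction of traces fuses spontaneously before injection
#' (cation-independent fusion).
#'
#' @param config A [sim_config()].
#' @return An `sv_simulation` list with elements `traces` (tibble: `trace_id`,
#'   `frame`, `time_s`, `label_intensity`, `content_intensity`),
#'   `ground_truth` (one row per trace: planted step frames, association
#'   class, fusion frame/category/latency/dwell), and `config`.
#' @export
#' @examples
#' sim <- simulate_traces(sim_config(n_traces = 5, seed = 42))
#' sim$ground_truth
simulate_traces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_frames <- cfg$n_frames
  inj <- cfg$injection_frame
  dt <- cfg$frame_interval
  time_s <- (seq_len(n_frames) - 1) * dt
  post_window <- (n_frames - inj) * dt
  if (post_window <= 0) {
    abort("no acquisition frames after injection.",
          class = "svfusion_parameter_error")
  }
  # association steps land clear of the +/-2-frame injection exclusion zone
  assoc_candidates <- seq(3L, inj - 3L)
  if (length(assoc_candidates) < 3L) {
    abort("injection arrives too early to place association steps.",
          class = "svfusion_parameter_error")
  }

  with_seed(cfg$seed, {
    gt <- vector("list", cfg$n_traces)
    tr <- vector("list", cfg$n_traces)
    for (i in seq_len(cfg$n_traces)) {
      multiple <- runif(1) < cfg$fraction_multiple_association
      n_steps <- if (multiple) sample(2:3, 1L, prob = c(0.8, 0.2)) else 1L
      step_frames <- sort(sample(assoc_candidates, n_steps))
      first_step <- step_frames[1]

      fusion_frame <- NA_integer_
      category <- NA_character_
      if (runif(1) < cfg$p_spontaneous_fusion && first_step < inj - 1L) {
        fusion_frame <- as.integer(
          sample(seq(first_step, inj - 1L), 1L))
        category <- "spontaneous"
      } else if (runif(1) < cfg$p_fusion) {
        t_evt <- sample_event_times_impl(cfg$fraction_fast, cfg$k_fast,
                                         cfg$k_slow, 1L, post_window)
        fusion_frame <- inj + as.integer(round(t_evt / dt))
        category <- if ((fusion_frame - inj) * dt <= 1) "immediate" else "delayed"
      }
      fusion_time <- if (is.na(fusion_frame)) NA_real_ else (fusion_frame - inj) * dt
      dwell <- if (is.na(fusion_frame)) NA_real_ else (fusion_frame - first_step) * dt

      label <- rep(cfg$label_baseline, n_frames)
      for (f in step_frames) {
        label[f:n_frames] <- label[f:n_frames] + cfg$association_step_amplitude
      }
      label[inj:n_frames] <- label[inj:n_frames] + cfg$free_dye_offset

      content <- rep(cfg$content_baseline, n_frames)
      if (!is.na(fusion_frame)) {
        idx <- fusion_frame:n_frames
        content[idx] <- content[idx] + cfg$content_rise_amplitude *
          exp(-cfg$content_decay_rate * (time_s[idx] - time_s[fusion_frame]))
      }
      if (cfg$noise_sigma > 0) {
        label <- label + rnorm(n_frames, sd = cfg$noise_sigma)
        content <- content + rnorm(n_frames, sd = cfg$noise_sigma)
      }

      gt[[i]] <- tibble(
        trace_id = i,
        n_steps = n_steps,
        class = if (n_steps > 1L) "multiple" else "single",
        step_frames = list(step_frames),
        fuses = !is.na(fusion_frame),
        fusion_frame = fusion_frame,
        fusion_time_s = fusion_time,
        fusion_category = category,
        dwell_time_s = dwell
      )
      tr[[i]] <- tibble(
        trace_id = i, frame = seq_len(n_frames), time_s = time_s,
        label_intensity = label, content_intensity = content
      )
    }
    structure(
      list(traces = list_rbind(tr), ground_truth = list_rbind(gt),
           config = cfg),
      class = "sv_simulation"
    )
  })
}

#' @export
print.sv_simulation <- function(x, ...) {
  gt <- x$ground_truth
  cat("<sv_simulation> ", nrow(gt), " traces (",
      sum(gt$class == "multiple"), " multiple-association, ",
      sum(gt$fuses), " fusing); seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write or read a simulation as plain-text files
#'
#' `write_simulation()` writes `traces.csv` (long table: trace_id, frame,
#' time_s, label_intensity, content_intensity), `ground_truth.json` and
#' `config.json` into `dir`. `read_trace_table()` reads a trace table back as
#' a tibble.
#'
#' @param sim An `sv_simulation`.
#' @param dir Output directory (created if absent).
#' @return `write_simulation()` returns the directory invisibly;
#'   `read_trace_table()` returns a tibble.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sv_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$traces, file.path(dir, "traces.csv"), row.names = FALSE)
  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_simulation
#' @param path Path to a `traces.csv`-style delimited file.
#' @export
read_trace_table <- function(path) {
  as_tibble(utils::read.csv(path))
}
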