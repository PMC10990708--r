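# Closed-form CDF of the window-truncated two-phase exponential mixture.
mixture_cdf <- function(t, p, kf, ks, window = Inf) {
  raw <- function(x) p * (1 - exp(-kf * x)) + (1 - p) * (1 - exp(-ks * x))
  if (is.finite(window)) raw(pmin(t, window)) / raw(window) else raw(t)
}

# Exhaustive minimizer of the penalized piecewise-constant cost over all
# changepoint sets of size <= max_cp. Independent of the dynamic program.
brute_force_partition <- function(x, penalty, max_cp = 3) {
  n <- length(x)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  seg_cost <- function(a, b) (s2[b + 1] - s2[a]) - (s1[b + 1] - s1[a])^2 / (b - a + 1)
  best_cost <- seg_cost(1, n) + penalty
  best_set <- integer(0)
  for (k in seq_len(max_cp)) {
    for (set in utils::combn(n - 1, k, simplify = FALSE)) {
      edges <- c(0, set, n)
      cost <- sum(vapply(seq_len(length(edges) - 1),
                         function(i) seg_cost(edges[i] + 1, edges[i + 1]),
                         numeric(1))) + (k + 1) * penalty
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best_set <- set
      }
    }
  }
  best_set
}

# Single-trace tibble with a flat label step (for injection detection) and a
# content fusion pulse, both optional.
make_trace <- function(n_frames = 120, dt = 0.2, noise = 0,
                       label_base = 20, label_step_frame = NULL,
                       label_step_amp = 10,
                       content_base = 10, fusion_frame = NULL,
                       fusion_amp = 8, decay_rate = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time_s <- (seq_len(n_frames) - 1) * dt
  label <- rep(label_base, n_frames)
  if (!is.null(label_step_frame)) {
    label[label_step_frame:n_frames] <- label[label_step_frame:n_frames] + label_step_amp
  }
  content <- rep(content_base, n_frames)
  if (!is.null(fusion_frame)) {
    idx <- fusion_frame:n_frames
    content[idx] <- content[idx] +
      fusion_amp * exp(-decay_rate * (time_s[idx] - time_s[fusion_frame]))
  }
  if (noise > 0) {
    label <- label + rnorm(n_frames, sd = noise)
    content <- content + rnorm(n_frames, sd = noise)
  }
  tibble::tibble(trace_id = 1L, frame = seq_len(n_frames), time_s = time_s,
                 label_intensity = label, content_intensity = content)
}

# Noiseless two-phase span-model histogram over left edges tt.
span_model_hist <- function(span_fast, span_slow, k_fast, k_slow,
                            bin_width = 0.2, window = 53) {
  tt <- seq(0, window - bin_width, by = bin_width)
  tibble::tibble(
    bin_left = tt, bin_right = tt + bin_width,
    count = span_fast * exp(-k_fast * tt) + span_slow * exp(-k_slow * tt)
  )
}
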