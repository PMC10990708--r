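test_that("pure-exponential limits of the latency mixture have the right means", {
  t_fast <- sample_event_times(1, k_fast = 0.3, k_slow = 0.3,
                               n = 10000, window = 1e6, seed = 11)
  expect_lt(abs(mean(t_fast) - 1 / 0.3) / (1 / 0.3), 0.02)

  t_slow <- sample_event_times(0, k_fast = 0.001, k_slow = 0.001,
                               n = 10000, window = 1e6, seed = 12)
  expect_lt(abs(mean(t_slow) - 1000) / 1000, 0.03)
})

test_that("first-second mass of the untruncated mixture matches the closed form", {
  # 0.7 * (1 - e^-0.3) + 0.3 * (1 - e^-0.001), computed by the oracle
  expected <- mixture_cdf(1, 0.7, 0.3, 0.001)
  t <- sample_event_times(0.7, 0.3, 0.001, n = 50000, window = 1e8, seed = 5)
  expect_equal(mean(t <= 1), expected, tolerance = 0.05)
  expect_lt(abs(mean(t <= 1) - expected), 0.01)
})

test_that("empirical CDF converges to the truncated-mixture CDF (KS < 0.01)", {
  n <- 1e5
  t <- sample_event_times(0.7, 0.3, 0.001, n = n, window = 53, seed = 99)
  ks <- max(abs(seq_len(n) / n - mixture_cdf(sort(t), 0.7, 0.3, 0.001, 53)))
  expect_lt(ks, 0.01)
  expect_true(all(t >= 0 & t <= 53))
})

test_that("latency sampling is reproducible and validates its parameters", {
  a <- sample_event_times(0.5, 1, 0.01, 100, 60, seed = 7)
  b <- sample_event_times(0.5, 1, 0.01, 100, 60, seed = 7)
  expect_identical(a, b)
  expect_error(sample_event_times(1.2, 1, 0.01, 10, 60),
               class = "svfusion_parameter_error")
  expect_error(sample_event_times(0.5, -1, 0.01, 10, 60),
               class = "svfusion_parameter_error")
  expect_error(sample_event_times(0.5, 0.01, 1, 10, 60),
               class = "svfusion_parameter_error")
})

test_that("histogram simulation follows the span-model Poisson law", {
  # zero spans: all-zero counts
  z <- simulate_histogram_counts(0, 0, 0.3, 0.001, seq(0, 5, 0.2), seed = 1)
  expect_true(all(z$count == 0))

  # Monte-Carlo mean of the first bin matches the model mean within 1%
  means <- vapply(1:10000, function(s) {
    simulate_histogram_counts(100, 0, 0.3, 0.001, c(0, 1), seed = s)$count
  }, numeric(1))
  expect_lt(abs(mean(means) - 100) / 100, 0.01)

  # Poisson property: per-bin sample mean ~ sample variance ~ model mean
  edges <- seq(0, 2, 0.5)
  draws <- vapply(1:3000, function(s) {
    simulate_histogram_counts(40, 10, 0.5, 0.01, edges, seed = 1000 + s)$count
  }, numeric(length(edges) - 1))
  mu <- simulate_histogram_counts(40, 10, 0.5, 0.01, edges, seed = 1)$model_mean
  expect_equal(rowMeans(draws), mu, tolerance = 0.05)
  expect_equal(apply(draws, 1, var), mu, tolerance = 0.1)

  # near-infinite fast rate: everything beyond the first bin is slow-term only
  fast_gone <- simulate_histogram_counts(70, 30, 1e3, 0.001,
                                         seq(0, 10, 1), seed = 3)
  expect_lt(max(abs(fast_gone$model_mean[-1] - 30 * exp(-0.001 * fast_gone$bin_left[-1]))),
            1e-6)

  expect_error(simulate_histogram_counts(-1, 0, 0.3, 0.001, c(0, 1)),
               class = "svfusion_parameter_error")
  expect_error(simulate_histogram_counts(1, 1, 0.3, 0.001, c(1, 1)),
               class = "svfusion_parameter_error")
})

test_that("bin-integrated means are the bin averages of the decay", {
  edges <- c(0, 2)
  h <- simulate_histogram_counts(100, 0, 0.5, 0.001, edges, seed = 1,
                                 bin_integrated = TRUE)
  expect_equal(h$model_mean, 100 * (1 - exp(-0.5 * 2)) / (0.5 * 2))
})

test_that("noiseless traces are exact two-level constructions", {
  cfg <- sim_config(n_traces = 6, noise_sigma = 0, p_fusion = 0,
                    p_spontaneous_fusion = 0, fraction_multiple_association = 0,
                    seed = 21)
  sim <- simulate_traces(cfg)
  gt <- sim$ground_truth
  expect_true(all(gt$class == "single"))
  for (i in gt$trace_id) {
    tr <- dplyr::filter(sim$traces, trace_id == i)
    sf <- gt$step_frames[[i]][1]
    # label: baseline, +step at the association frame, +free dye at injection
    expected <- cfg$label_baseline +
      cfg$association_step_amplitude * (tr$frame >= sf) +
      cfg$free_dye_offset * (tr$frame >= cfg$injection_frame)
    expect_identical(tr$label_intensity, expected)
    expect_true(all(tr$content_intensity == cfg$content_baseline))
  }
})

test_that("without spontaneous fusion no content rise precedes injection", {
  cfg <- sim_config(n_traces = 40, noise_sigma = 0, p_spontaneous_fusion = 0,
                    p_fusion = 1, seed = 8)
  sim <- simulate_traces(cfg)
  pre <- dplyr::filter(sim$traces, frame < cfg$injection_frame)
  expect_true(all(pre$content_intensity == cfg$content_baseline))
  expect_true(all(sim$ground_truth$fusion_time_s >= 0))
})

test_that("every ground-truth fusion frame maps to a content rise at zero noise", {
  cfg <- sim_config(n_traces = 30, noise_sigma = 0, p_fusion = 0.8, seed = 13)
  sim <- simulate_traces(cfg)
  fused <- dplyr::filter(sim$ground_truth, fuses)
  expect_gt(nrow(fused), 0)
  for (i in seq_len(nrow(fused))) {
    tr <- dplyr::filter(sim$traces, trace_id == fused$trace_id[i])
    f <- fused$fusion_frame[i]
    expect_equal(tr$content_intensity[f] - cfg$content_baseline,
                 cfg$content_rise_amplitude)
    if (f > 1) expect_lt(tr$content_intensity[f - 1], tr$content_intensity[f])
  }
})

test_that("multiple-association counts behave binomially across seeds", {
  counts <- vapply(1:100, function(s) {
    gt <- simulate_traces(sim_config(n_traces = 200, noise_sigma = 0,
                                     fraction_multiple_association = 0.05,
                                     p_fusion = 0, seed = s))$ground_truth
    sum(gt$class == "multiple")
  }, numeric(1))
  # Binomial(200, 0.05): mean 10, var 9.5
  expect_equal(mean(counts), 10, tolerance = 0.1)
  expect_equal(var(counts), 9.5, tolerance = 0.35)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  a <- simulate_traces(sim_config(n_traces = 10, seed = 4))
  b <- simulate_traces(sim_config(n_traces = 10, seed = 4))
  expect_identical(a$traces, b$traces)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_error(sim_config(n_traces = 0), class = "svfusion_parameter_error")
})

test_that("simulations round-trip through the plain-text writers", {
  sim <- simulate_traces(sim_config(n_traces = 3, seed = 2))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("traces.csv", "ground_truth.json",
                                               "config.json")))))
  back <- read_trace_table(file.path(dir, "traces.csv"))
  expect_equal(nrow(back), nrow(sim$traces))
  expect_equal(back$label_intensity, sim$traces$label_intensity,
               tolerance = 1e-12)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$seed, 2L)
})
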