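test_that("noiseless steps are recovered exactly", {
  one <- c(rep(0, 49), rep(10, 51))
  s <- detect_steps(one, frame_interval = 0.2)
  expect_equal(nrow(s), 1)
  expect_equal(s$frame, 50L)
  expect_equal(s$amplitude, 10)
  expect_equal(s$sign, "+")

  stair <- c(rep(1, 19), rep(4, 20), rep(9, 21))
  s2 <- detect_steps(stair, frame_interval = 0.2)
  expect_equal(s2$frame, c(20L, 40L))
  expect_equal(s2$amplitude, c(3, 5))
  expect_false(is.unsorted(s2$frame))

  expect_equal(nrow(detect_steps(rep(5, 60))), 0)
  expect_error(detect_steps(rep(1, 5)), class = "svfusion_input_error")
})

test_that("the dynamic program matches exhaustive search on small noiseless instances", {
  set.seed(301)
  for (rep in 1:6) {
    n <- 60
    n_cp <- sample(0:3, 1)
    cps <- sort(sample(5:(n - 5), n_cp))
    levels <- cumsum(c(0, sample(c(-1, 1), n_cp, replace = TRUE) *
                          runif(n_cp, 3, 8)))
    x <- rep(levels, diff(c(0, cps, n))) + rnorm(n, sd = 0.3)
    sigma <- estimate_noise_sigma(x)
    penalty <- 2 * sigma^2 * log(n)
    oracle <- brute_force_partition(x, penalty, max_cp = 3)
    dp <- svfusion:::optimal_partition(x, penalty)
    expect_equal(dp, oracle)
  }
})

test_that("step detection is translation- and scale-equivariant", {
  base <- c(rep(2, 30), rep(9, 30), rep(14, 40))
  s0 <- detect_steps(base)
  shifted <- c(rep(2, 7), base)[1:100]
  s1 <- detect_steps(shifted)
  expect_equal(s1$frame, s0$frame + 7L)
  expect_equal(s1$amplitude, s0$amplitude)

  s2 <- detect_steps(3 * base)
  expect_equal(s2$frame, s0$frame)
  expect_equal(s2$amplitude, 3 * s0$amplitude)
})

test_that("detection and classification degrade monotonically with lower SNR", {
  rate_at <- function(amp) {
    hits <- vapply(1:120, function(i) {
      set.seed(5000 + 120 * amp + i)
      x <- c(rep(0, 60), rep(amp, 60)) + rnorm(120)
      s <- detect_steps(x, min_step_sigma = 4)
      nrow(s) > 0 && any(abs(s$frame - 61L) <= 1 & s$amplitude > 0)
    }, logical(1))
    mean(hits)
  }
  r <- vapply(c(4, 6, 10), rate_at, numeric(1))
  expect_true(all(diff(r) >= -0.05))
  expect_gte(r[3], r[1])
})

test_that("injection detection locates the free-dye step", {
  tr <- make_trace(n_frames = 100, label_step_frame = 35)
  inj <- detect_injection(tr, n_baseline_frames = 30)
  expect_true(inj$detected)
  expect_equal(inj$frame, 35L)

  set.seed(44)
  flat <- make_trace(n_frames = 100, noise = 1)
  inj2 <- detect_injection(flat, n_baseline_frames = 30)
  expect_false(inj2$detected)

  zero <- make_trace(n_frames = 100, label_base = 0, content_base = 0)
  expect_error(detect_injection(zero), class = "svfusion_estimation_error")

  # noisy cohort at SNR 10: located within +/-1 frame in >= 99% of traces
  hits <- vapply(1:500, function(i) {
    tr <- make_trace(n_frames = 100, label_step_frame = 35,
                     label_step_amp = 10, noise = 1, seed = 7000 + i)
    inj <- detect_injection(tr, n_baseline_frames = 30)
    inj$detected && abs(inj$frame - 35L) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("association classification counts positive non-injection steps", {
  one <- tibble::tibble(frame = 12L, amplitude = 6, sign = "+")
  a1 <- classify_association(one)
  expect_equal(a1$class, "single")
  expect_equal(a1$n_steps, 1)

  three <- tibble::tibble(frame = c(10L, 20L, 30L), amplitude = c(5, 6, 7),
                          sign = "+")
  a3 <- classify_association(three)
  expect_equal(a3$class, "multiple")
  expect_equal(a3$n_steps, 3)
  expect_equal(a3$first_step_frame, 10L)

  # the free-dye step near the injection frame is excluded; departures ignored
  inj <- tibble::tibble(detected = TRUE, frame = 36L, time_s = 7, score = 20)
  steps <- tibble::tibble(frame = c(12L, 35L, 50L), amplitude = c(6, 10, -5),
                          sign = c("+", "+", "-"))
  a <- classify_association(steps, inj)
  expect_equal(a$n_steps, 1)
  expect_equal(a$class, "single")

  only_inj <- tibble::tibble(frame = 36L, amplitude = 10, sign = "+")
  expect_null(classify_association(only_inj, inj))
})

test_that("fusion detection requires a rise followed by decay", {
  flat <- make_trace(n_frames = 100)
  expect_null(detect_fusion(flat))

  inj <- tibble::tibble(detected = TRUE, frame = 36L, time_s = 7, score = 20)
  # rise 2 frames after injection = 0.4 s -> immediate
  tr <- make_trace(n_frames = 200, fusion_frame = 38)
  fu <- detect_fusion(tr, inj)
  expect_equal(fu$fusion_frame, 38L)
  expect_equal(fu$time_after_injection_s, 0.4)
  expect_equal(fu$category, "immediate")

  # a pure content step with no decay is not a fusion
  step_only <- make_trace(n_frames = 100)
  step_only$content_intensity[50:100] <- step_only$content_intensity[50:100] + 8
  expect_null(detect_fusion(step_only))
})

test_that("cation-independent fusion reproduces printed dwell times", {
  # association at frame 10, fusion 127 frames later on a 0.1 s grid: a
  # 12.7 s dwell in a trace with no injection present
  dt <- 0.1
  n <- 300
  tr <- make_trace(n_frames = n, dt = dt, fusion_frame = 137, decay_rate = 0.5)
  fu <- detect_fusion(tr, injection = NULL)
  expect_equal(fu$category, "cation_independent")
  assoc <- tibble::tibble(first_step_frame = 10L)
  expect_equal(dwell_time(assoc, fu, dt), 12.7)

  # no injection mark at all -> cation-independent regardless of time
  expect_true(is.na(fu$time_after_injection_s))
})

test_that("dwell time is the frame difference times the frame interval", {
  a <- tibble::tibble(first_step_frame = 25L)
  f <- tibble::tibble(fusion_frame = 25L)
  expect_equal(dwell_time(a, f, 0.2), 0) # fusion immediately upon association

  a2 <- tibble::tibble(first_step_frame = 10L)
  f2 <- tibble::tibble(fusion_frame = 128L)
  expect_equal(dwell_time(a2, f2, 0.2), 23.6)

  f3 <- tibble::tibble(fusion_frame = 9L)
  expect_error(dwell_time(a2, f3, 0.2), class = "svfusion_ordering_error")
})

test_that("detect_events recovers the planted ground truth end to end", {
  sim <- simulate_traces(sim_config(n_traces = 60, seed = 17,
                                    association_step_amplitude = 8))
  ev <- detect_events(sim$traces)
  gt <- sim$ground_truth
  inj <- attr(ev, "injection")
  expect_true(inj$detected)
  expect_equal(inj$frame, sim$config$injection_frame)

  expect_gte(mean(gt$fuses == ev$fused), 0.95)
  both <- gt$fuses & ev$fused
  expect_gte(mean(abs(gt$fusion_frame[both] - ev$fusion_frame[both]) <= 1), 0.95)
  expect_gte(mean(gt$class == ev$class, na.rm = TRUE), 0.95)
  # spontaneous truth maps to the cation-independent detection category
  gt_cat <- ifelse(gt$fusion_category == "spontaneous", "cation_independent",
                   gt$fusion_category)
  agree <- both & !is.na(gt_cat)
  expect_gte(mean(gt_cat[agree] == ev$fusion_category[agree]), 0.95)
})
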