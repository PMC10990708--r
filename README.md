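# svfusion

Analysis of single-vesicle content-mixing fusion assays recorded by TIRF
microscopy, for labs running (or reanalyzing) hybrid vesicle-fusion
experiments: synaptic vesicles docking onto tethered plasma-membrane-mimic
liposomes, with fusion triggered by Ca²⁺ injection and read out as
content-dye dequenching.

Each tethered spot yields a two-channel time trace (0.2 s frames): a label
channel (Alexa-647 on the vesicles) that rises in discrete steps as vesicles
dock, and a content channel (sulforhodamine B) that shows a rise-then-decay
pulse at membrane merger. Free dye co-injected with the cation steps up the
label channel of every trace, marking injection arrival (t = 0 for fusion
latencies). The package covers the full path from traces to statistics:

* **Event detection** — exact penalized changepoint fitting finds
  association steps (single vs. multiple docking), the injection frame, and
  content-channel fusion events with dwell times; fusion events are
  categorized as immediate (≤ 1 s after injection), delayed, or
  cation-independent.
* **Kinetics** — injection-normalized event-time histograms and cumulative
  curves; two-phase exponential decay fits in the span parameterization with
  plateau fixed at zero,

  $$c(t) = S_f e^{-k_f t} + S_s e^{-k_s t}, \qquad
    \%\,\text{fast} = 100\, S_f / (S_f + S_s),$$

  by deterministic multistart Levenberg–Marquardt with canonical labelling
  (always $k_f \ge k_s$);
* **Synchronization statistics** — the fraction of all fusion events in the
  first second after injection, with bootstrap-subset mean/SD/SEM and
  pairwise unpaired two-tailed Student's t-tests across conditions;
* **Morphometry** — vesicle diameters from traced areas via
  $d = 2\sqrt{A/\pi}$, with arithmetic and geometric (DLS-style) summaries;
* **A ground-truthed synthetic generator** — two-channel traces with planted
  association steps, injection offset, two-phase fusion latencies, rare
  spontaneous fusion and Gaussian camera noise, so every stage is testable
  without raw movies.

## Worked example

```r
library(svfusion)

sim <- simulate_traces(sim_config(n_traces = 400, fraction_fast = 0.7,
                                  k_fast = 0.3, k_slow = 0.02,
                                  p_fusion = 0.6, seed = 42))
sim
#> <sv_simulation> 400 traces (15 multiple-association, 250 fusing); seed 42

events <- detect_events(sim$traces)
attr(events, "injection")
#> # A tibble: 1 × 4
#>   detected frame time_s score
#> 1 TRUE        36      7  156.
```

The injection is found at frame 36 (7.0 s), exactly where the generator put
it. Post-injection fusion latencies then feed the kinetics:

```r
times <- events$fusion_time_s[events$fused & !is.na(events$fusion_time_s) &
                                events$fusion_time_s >= 0]
fit <- fit_two_phase_decay(event_time_histogram(times, bin_width = 1, window = 53))
fit
#> <two_phase_fit> 99.3% fast (k_fast = 0.2601 /s), 0.7% slow (k_slow = 1e-06 /s); R^2 = 0.979

synchronization(times)
#> # A tibble: 1 × 4
#>   fraction_first_window window_s n_in_window n_events
#> 1                 0.239        1          59      247

bootstrap_statistic(times, subset_size = 20, seed = 1)
#> <bootstrap_result> mean 0.29, SD 0.09944, SEM 0.03145 (10 subsets of 20, without replacement)
```

247 of the 250 planted fusions are recovered; the fitted fast rate 0.26 s⁻¹
tracks the generating 0.3 s⁻¹, and the fit is almost entirely fast-phase:
at these rate scales very few slow-mixture latencies fall inside the 53-s
window, so the in-window histogram is nearly single-exponential (the span
share of a fit and the event share of the mixture are different quantities —
see the vignette). About 24% of events land in the first second, with a
bootstrap SEM of ~3 points.

Two-phase structure is explicit in the span-model recovery study, here at a
70%/30% span split with rates 0.3/0.001 s⁻¹ and ~500 expected events:

```r
study <- decay_recovery_study(70, k_fast = 0.3, k_slow = 0.001, seeds = 1:20)
median(study$k_fast)        # 0.2802
median(study$percent_fast)  # 68.85
```

`run_pipeline(default_run_config(seed = 1))` chains all stages over a
four-condition Ca²⁺/Mg²⁺ panel and writes a deterministic JSON report;
`condition_presets()` lists the panel's reference parameters.

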