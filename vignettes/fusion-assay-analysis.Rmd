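---
title: "Single-vesicle fusion assay analysis: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-vesicle fusion assay analysis: models, detectors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(svfusion)
```

## The assay and its data

In a single-vesicle content-mixing fusion assay, acceptor liposomes that
mimic the presynaptic plasma membrane (reconstituted with syntaxin-1A and
SNAP-25A and loaded with self-quenched sulforhodamine B) are tethered in a
TIRF flow cell. Labeled synaptic vesicles are flowed in; each tethered spot
is recorded as a two-channel fluorescence time trace:

* the **label channel** (Alexa-647 on the synaptic vesicles) rises in
  discrete steps when a vesicle docks onto a tethered acceptor — one step per
  docking vesicle;
* the **content channel** (sulforhodamine B) shows a dequenching rise at the
  moment of membrane merger, followed by decay as the dye is lost or
  bleaches.

After an association phase, acquisition restarts with a ~30-frame baseline,
then a Ca²⁺ (or Mg²⁺ control) solution is injected together with free
Alexa-647 dye: the free dye raises the label channel of *every* trace in a
single step, marking the injection arrival that defines $t = 0$ for fusion
latencies. Frames are 0.2 s apart, so the "first second" after injection is
about 5 frames.

`svfusion` implements the full trace-to-statistics path: event detection,
injection-normalized event-time kinetics with a two-phase exponential decay
fit, the first-second synchronization statistic with bootstrap-subset
uncertainty and pairwise t-tests, and vesicle morphometry. Because raw
movies are rarely at hand, the package ships a ground-truthed synthetic
trace generator that emulates exactly the structure above; every detector
and estimator in the package is validated against it.

## The synthetic generator

`sim_config()` + `simulate_traces()` generate per-frame traces with known
ground truth. What is emulated, per trace:

* a constant baseline in both channels, with additive Gaussian camera noise
  (`noise_sigma`, the unit in which step thresholds are expressed);
* one association step before injection (a fraction
  `fraction_multiple_association`, default 5%, carries 2–3 steps);
* the free-dye offset step at the injection frame
  (`injection_time`, default 7 s; frame interval 0.2 s);
* for fusing traces, a content-channel rise of `content_rise_amplitude`
  followed by exponential decay at `content_decay_rate` (0.5 s⁻¹ default — a
  visible but not instantaneous loss);
* post-injection fusion latencies drawn from the two-phase exponential
  mixture (`fraction_fast`, `k_fast`, `k_slow`), truncated to the remaining
  acquisition window **by rejection sampling** — simple and exactly the
  truncated density, at the price of re-draws (cheap at these rates);
* a small probability `p_spontaneous_fusion` (1% default) of
  cation-independent fusion before injection, mirroring the rare
  Ca²⁺-independent events seen in association movies.

The spec-level configuration has no field for *how many* traces fuse after
injection, yet fusing and non-fusing traces must coexist for the detectors
to be testable; we added `p_fusion` (default 0.5) as an explicit generator
knob for this.

What is *not* emulated — and therefore what passing tests do not establish
about real data: spot detection and drift on raw movies, EMCCD excess noise
(noise is plain Gaussian), partial labeling efficiency (association counts
are raw counts, exactly as in the assay's own analysis), photophysics beyond
one decay, and channel registration. The generator's defaults are the study
conditions; they are not adjusted per experiment.

```{r simulate}
sim <- simulate_traces(sim_config(n_traces = 12, seed = 42))
sim
autoplot(sim)
```

## Event detection

**Step detection** (`detect_steps()`) is exact penalized least-squares
changepoint fitting: the signal is modelled as piecewise constant, segment
costs are squared error, and each additional segment pays a penalty
$2\hat\sigma^2\log n$, with $\hat\sigma$ the noise sigma estimated from the
median absolute successive difference (robust to the steps themselves). The
dynamic program is exact (optimal partitioning, $O(n^2)$ — traces are a few
hundred frames, so this costs milliseconds), deterministic, and needs no
training. Steps below `min_step_sigma` (default 4) noise sigmas are pruned.
Two pruning semantics exist because two signal shapes exist:

* *staircase* signals (label channel): a discarded sub-threshold step merges
  its flanking segments so surviving amplitudes stay consistent;
* *pulse* signals (content channel): merging is destructive — absorbing the
  sub-threshold decay steps after a fusion rise drags the post-rise level
  back to baseline until the rise itself disappears — so `detect_fusion()`
  prunes without merging and then requires a negative least-squares slope
  over ≥ 5 frames after the rise (the decay signature).

On noiseless input $\hat\sigma = 0$; the penalty then falls back to a tiny
positive value so that splitting a constant segment (zero cost saving) is
still disfavoured while any genuine step is recovered exactly. The test
suite checks the dynamic program against exhaustive enumeration of all
changepoint sets of size ≤ 3 on 60-frame traces.

**Injection detection.** Per trace, `detect_injection()` flags the first
frame exceeding the baseline mean by `threshold_sigma` sigmas with ≥ 3-frame
persistence. Across a trace set, `detect_events()` instead locates the
largest positive step of the *median* label trace: the free-dye step is
common to all traces whereas association steps are trace-specific, so the
median series isolates it — this is robust even though association steps may
fall inside the nominal baseline window. Association steps within ±2 frames
of the injection mark are excluded from association counting (the free dye
is a global background rise, not a docking).

**Classification.** One surviving positive label step → single association;
two or more → multiple. Negative steps (departures) are recorded but never
decrement the count — the package takes no stance on undocking semantics.
Fusion events are *immediate* within 1 s of injection (the synchronization
window; the underlying distinction in the field is qualitative, so we
operationalize it at the same 1-s cutoff), *delayed* after it, and
*cation-independent* before injection or in traces with no injection.

```{r detect}
events <- detect_events(sim$traces)
attr(events, "injection")
dplyr::count(events, class, fusion_category)
```

## Kinetics: histogram, two-phase decay, synchronization

Post-injection latencies (pre-injection events are cation-independent by
definition and are excluded) are binned into half-open bins over a 53-s
window — the acquisition minute minus the 7-s injection offset. The 7-s
offset seen in figure-style displays is presentation only; all internal
times are relative to injection. Bin width is configurable (default one
frame, 0.2 s); the fit is evaluated at left bin edges, matching how a decay
curve is conventionally laid over histogram bars, and the generator's
Poisson bin means use the same convention (a bin-integrated option exists
behind a flag).

The fitted model is the span (amplitude) parameterization with plateau
fixed at zero,

$$
c(t) = S_f\,e^{-k_f t} + S_s\,e^{-k_s t},
\qquad \text{percent fast} = 100\,\frac{S_f}{S_f+S_s},
$$

the standard output convention of commercial nonlinear-regression fits of
such histograms; a density parameterization would weight components by
$S/k$ instead. Fitting is unweighted least squares (mirroring conventional
practice for these histograms; a Poisson-style weighting option exists but
is biased high at low counts because it over-trusts empty tail bins).
Optimization is multistart Levenberg–Marquardt over a fixed grid of rate
starts ($k_f \in \{0.05, 0.3, 1, 3\}$ s⁻¹, $k_s \in \{0.001, 0.01\}$ s⁻¹,
spans started from the first and last bins), bounded at zero, best SSE
winning with exact ties broken toward the larger fast rate — deterministic
for a given histogram. Two canonicalizations keep the labels meaningful
regardless of optimizer internals:

* components are swapped if needed so $k_f \ge k_s$ always holds;
* a fit whose two rates agree to within $10^{-4}$ relative, or whose
  fast-labelled span is numerically zero, is a single-exponential fit in
  disguise — its span split is arbitrary — and is reported as 100% fast.

Fits with fewer than 20 events are flagged `unreliable` (the assay's own
low-count control condition illustrates how little such fits constrain);
fewer than 6 non-empty bins is an error.

One subtlety worth stating: the **span share is not the event share**. With
rates $k_f = 0.3$ and $k_s = 0.001$ s⁻¹, a latency mixture needs only a few
percent of *in-window events* in the slow component to produce a large slow
*span*, and conversely a 70% fast *event* fraction yields an almost
single-phase in-window histogram. The printed percent-fast of a span fit,
the first-second fraction, and the mixture weight are three different
quantities; the package keeps them distinct (`fraction_fast` configures the
event mixture, `percent_fast` reports the span fit).

`synchronization()` is the exact counted fraction of events in the first
second out of all events observed in the acquisition; `cumulative_event_curve()`
is the right-continuous empirical CDF.

```{r kinetics}
times <- events$fusion_time_s[events$fused & !is.na(events$fusion_time_s) &
                                events$fusion_time_s >= 0]
synchronization(times)
```

## Parameter recovery and identifiability

`decay_recovery_study()` plants known span-model parameters, simulates
Poisson bin counts scaled to ~500 expected events over the 53-s window
(0.2-s bins), refits, and reports the recovered parameters per seed. At the
condition panel of `condition_presets()`:

* well-separated rate pairs (0.3 vs 0.001 s⁻¹; 0.7 vs 0.005 s⁻¹) are
  recovered with median fast-rate error under ~10% and median percent-fast
  within ~2 points over 20 seeds;
* the control-condition pair 0.05 vs 0.007 s⁻¹ — only a 7× separation — is
  **weakly identifiable** at these counts: single-seed estimates scatter
  over orders of magnitude and even the 20-seed median is biased. This is a
  property of the data size and rate geometry, not of the optimizer; the
  recovery study reports it honestly rather than masking it.

```{r recovery}
study <- decay_recovery_study(70, k_fast = 0.3, k_slow = 0.001, seeds = 1:20)
c(median_k_fast = median(study$k_fast),
  median_percent_fast = median(study$percent_fast))
```

The test suite uses 20 seeds per condition, 200-trace cohorts per SNR level
for the detector studies, and 10⁴ replicates for the t-test calibration —
sizes chosen so each study estimates its rate with useful precision while
the whole suite stays quick to run.

## Bootstrap subsets and pairwise tests

When per-experiment event counts are too small for replicate-level
statistics, an uncertainty is attached to the synchronization fraction by
subset resampling: `n_subsets` (default 10, mirroring common practice —
though the SEM over 10 subsets is itself noisy, and more subsets are
recommended when runtime allows) random subsets of `subset_size` event
times, drawn with or without replacement, each reduced to its first-second
fraction; the summary is their mean, SD, and SEM = SD/√`n_subsets`. The
"items" being resampled are individual fusion-event times — the only
reading under which subset sizes of 20 (Ca²⁺ conditions) and 10 (the
smaller Mg²⁺ control) make sense against condition totals in the tens to
low hundreds. Subsets are drawn independently (not as a partition); with
replacement and without replacement give similar summaries in practice.

Condition pairs are compared by unpaired two-tailed Student's (pooled
variance) t-tests on the subset statistics, with Welch's variant behind a
flag. No multiple-testing correction is applied across the pairwise
comparisons — deliberately mirroring how such condition panels are usually
reported; users who need family-wise control should adjust the returned
p-values themselves. Degenerate inputs follow explicit conventions: zero
pooled variance with equal means gives $t = 0, p = 1$; with unequal means
the statistic is undefined and an error is raised.

## Morphometry

Vesicle diameters come from traced cross-sectional areas via the circle
formula $d = 2\sqrt{A/\pi}$. Summaries report the arithmetic mean with both
SD and SEM (publications vary in which they print; both are provided), and
the geometric mean `exp(mean(log d))` with its geometric SD factor — the
quantity dynamic light scattering instruments report, always ≤ the
arithmetic mean. Curation of which vesicles to trace (excluding deformed
particles, sampling micrographs) is a judgment call made upstream; the
module accepts any area table and does not automate exclusions.

## Pipeline and determinism

`run_pipeline()` chains simulate → detect → kinetics → stats (and optional
morphometry) over a multi-condition configuration (an R list or a YAML
file), writing a single JSON report plus per-condition event tables. Every
random draw descends from the configured seed (per-condition seeds are
derived from it), and local RNG state is isolated, so identical
configuration and seed reproduce the report byte for byte. A failing stage
aborts with the stage and condition named.

## Known limitations

* The step detector assumes piecewise-constant levels between events;
  gradual drifts or slow ramps are not modelled and would be segmented into
  spurious small steps (mostly removed by the sigma threshold).
* Close rate pairs in the two-phase fit are weakly identifiable at realistic
  event counts (see above); `r_squared` alone does not reveal this.
* The bootstrap SEM over 10 subsets is itself a noisy estimate.
* Association counts are raw: partial labeling means true association
  numbers are undercounted, and nothing in the package corrects for it.
* The generator's Gaussian noise understates the heavy tail of EMCCD noise;
  detector thresholds calibrated here may need to be raised on real data.
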