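---
title: "Up/down-state segmentation and thalamo-cortical spike-timing analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Up/down-state segmentation and thalamo-cortical spike-timing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(slowstates)
```

This vignette explains the models behind each pipeline stage, the tunable
parameters and their defaults, the design choices made where the method left
room, what the synthetic-data generator does and does not emulate, and the
known limitations. No empirical claim here goes beyond what the package's
test suite and `scripts/acceptance.R` themselves compute.

## The problem

Under deep anesthesia (and in slow-wave sleep), cortical networks alternate
at 0.2–1 Hz between a depolarized, active **up state** and a hyperpolarized,
silent **down state**. In depth LFP recordings the down state appears as a
depth-positive wave and the up state as a depth-negative wave. The analyses
in this package address a specific physiological question: whether firing in
the somatosensory thalamus (VPM multi-unit activity) drives the spiking of
cortical PV interneurons during down states — quantified by phase locking,
by a surrogate-calibrated spike-triggered rate analysis, and by the latency
of down-to-up transitions evoked by optogenetic PV inhibition.

## Up/down-state segmentation

### Evidence variables

Two decision variables are computed at the 1 kHz working rate (the raw LFP
is first low-passed at 500 Hz with a zero-phase order-4 elliptic filter and
decimated):

* **Delta phase evidence** `S_delta(t)`. The configured low-frequency bands
  (defaults `[0, 1]` and `[1, 2]` Hz) carry state information in their
  instantaneous phase: with the depth convention above, phase 0 is the
  depth-positive (down) peak and the up state clusters near 180°. Two
  functional forms are provided. The `"cosine"` form is the simplest
  monotone phase evidence, the per-band raised cosine
  `e_b = (1 + cos(φ_b − φ_up))/2` averaged across bands. The default
  `"analytic"` form sums the per-band analytic signals — for contiguous
  bands this is the analytic signal of the union band — and maps the summed
  phase through a normalized logistic of `cos(φ − φ_up)`. The reason for
  the default is empirical and mechanistic: narrowband phases at true state
  boundaries scatter across cycles by tens of degrees (circular resultant
  R ≈ 0.65–0.83 at up-state onsets on synthetic sessions), whereas the
  union-band phase is pinned by the waveform's harmonics (R ≈ 1.00), so
  the evidence transition is tied to the actual transition of each cycle
  rather than to an average cycle.
* **Beta/low-gamma power evidence** `S_betagamma(t)`. Running RMS of the
  `[10, 51]` Hz band in a 5-ms centered frame, smoothed with a 50-ms
  centered boxcar, normalized so the minimum maps to 0 and the 95th
  percentile to 1, with larger values clipped. The normalization makes the
  evidence exactly invariant to amplitude rescaling of the raw LFP.

`S_comb(t)` is their average. Two numerical parameters of the analytic
evidence deserve comment, because they were chosen by validation against
the generator's ground truth rather than derived:

* **sharpness** (default 8): steepness of the logistic map. Steeper maps
  concentrate the evidence transition at the phase crossing, shrinking the
  indeterminate sweep band at each boundary.
* **crossing offset** (default 0.2): the phase at which the evidence passes
  0.5 is `cos(φ − φ_up) = 0.2` rather than 0. The centered 50-ms smoothing
  of the power evidence bleeds the broadband transition burst roughly 25 ms
  into the flanking down state on each side, dilating detected up states
  symmetrically; the offset shrinks the phase region scored as up state by
  the same amount. Both values were fixed after a coarse scan on 600-s
  synthetic sessions and validated unchanged on held-out seeds; with them
  the default pipeline reaches ~97% up/down sample agreement and ~20 ms
  median boundary error on the generator's default conditions (recomputed
  by the acceptance script on every run).

### Mixture thresholding and post-processing

The distribution of `S_comb` (excluding the top 5th percentile) is fitted
with a three-component Gaussian mixture by EM; components ordered by mean
represent down, indeterminate and up states. Thresholds are
`θ_up = μ_UP − 2σ_UP` and `θ_down = μ_DOWN + 2σ_DOWN`; a fit with
`θ_down ≥ θ_up` is flagged degenerate and refuses to segment. Numerical
choices:

* EM runs on a 512-bin histogram of the retained samples (weighted EM).
  This is equivalent to sample EM up to binning resolution and makes the
  fit essentially instantaneous on 600-s recordings.
* Initialization is quantile-based (10th/50th/90th percentiles), with
  seeded jitter over 10 restarts; the best log-likelihood wins. Convergence
  at `Δlog L < 1e-8` or 500 iterations.
* Samples exactly at a threshold go to indeterminate (strict inequalities).

Post-processing applies two rules once, in this order: indeterminate gaps
shorter than 50 ms flanked by two same-label states are merged into that
label; then up/down runs shorter than 100 ms are relabeled indeterminate.
This order never creates sub-100-ms states.

For recordings under changed conditions (e.g. after pharmacological
manipulation) the mixture should be re-fitted on the new recording; the
latency pipeline, by contrast, deliberately reuses the control threshold
(see below).

## Spike detection

* **Juxtasomal traces**: zero-phase 300-Hz high-pass, hard threshold at
  6 × estimated noise SD, one spike per supra-threshold excursion at its
  positive peak, 1-ms refractory resolution keeping the larger peak (a
  spike's waveform ringing can split one excursion in two).
* **Multi-unit traces**: zero-phase `[300, 3000]` Hz band-pass; pairs of
  neighboring relative extrema within a 3-ms peak lifetime whose
  peak-to-peak amplitude exceeds 8.5 × noise SD (configurable in the
  conventional 8–9 range), time-stamped at the negative peak, 1-ms
  refractory. Two robustness rules matter in practice: each extremum can
  belong to at most one spike event (pairs are accepted greedily by
  amplitude), and the trough must carry at least half of the pair's
  peak-to-peak excursion — both reject filter-ringing rebound pairs that
  would otherwise double-count spikes. The second rule assumes
  negative-dominant extracellular waveforms, which is also the convention
  by which timestamps go to negative peaks.
* The noise SD estimator defaults to `median(|x|)/0.6745`, robust to spike
  contamination; the raw standard deviation is available for parity checks.
  Both make detection exactly invariant to amplitude rescaling.

## Phase locking

Phases come from the angle of the analytic signal of the `[0.1, 4]` Hz
filtered LFP. Because asymmetric slow-wave shapes make the raw phase
distribution non-uniform across time, all phases are rescaled by the
empirical CDF of the full trace (`φ' = 2πF(φ) − π`) before any statistic;
the CDF uses all time samples, with linear interpolation between sorted
values. Reported statistics: Rayleigh test (standard closed-form
approximation; locking is conventionally declared at p < 0.01), preferred
phase (circular mean, degrees in [0, 360)), locking strength (one minus the
circular variance, i.e. the mean resultant length), and a maximum-likelihood
von Mises fit (`κ` solves `A1(κ) = R̄` by Newton iteration, capped at 1e3).
Histograms default to 18 bins of 20°, configurable.

State-restricted distributions keep spikes of one state whose phase lies in
the state's characteristic range — `[95, 255]°` for up and `[295, 75]°`
(wrapping through 0) for down states, the conventional 5th–95th percentile
ranges — rescale within-range phases by the within-range CDF of same-state
samples (indeterminate samples excluded), and also express each spike as a
relative time within its interval (0 = state start, 1 = end). On synthetic
sessions the fixed ranges trim somewhat more than 10% because the generated
phase is very tightly coupled to state boundaries; the trim concentrates at
interval edges, which slightly depletes the first and last relative-time
bins. The test suite therefore validates relative-time uniformity on the
full circle and checks only central tendency under the trimmed range.

## Spike-triggered VPM rate and the surrogate null

The target train's instantaneous firing rate is the spike train convolved
with a unit-area Gaussian kernel (default SD 12.5 ms ≈ 20-Hz low-pass; the
scan range 1.25–12.5 ms is exposed in the parameters). Around each PV
trigger spike fired in a down state the pipeline reports the triggered mean
± SEM curve and mean rates in 100-ms pre/post windows.

The null distribution is built from 100 surrogate spike sets constrained as
follows: spikes are placed only in PV-silent down states; each surrogate
carries exactly the real number of down-state PV spikes; the real spike
phases are **permuted** across surrogate spikes, so the down-state
phase-of-firing distribution is preserved exactly; the number of sampled
states is capped at the real number of PV-active down states and the
per-state count at the real maximum. Two design choices were made for
calibration, measured on a few hundred uncoupled synthetic sessions:

* Silent down states are sampled **duration-weighted** (uniform per unit
  time). PV-silent states are biased short, and short down states have a
  higher mean phase-gain VPM rate, so uniform per-state sampling biased the
  null mean upward.
* Phase **permutation** rather than bootstrap resampling removes a
  resampling overdispersion of the surrogate distribution.

With both, the null z-score distribution is close to standard normal and
the one-tailed test (`p = 1 − Φ(z)`) rejects at very close to its nominal
5% rate, while a causal VPM→PV coupling at the generator's default strength
is detected essentially always (both rates are recomputed by the acceptance
script). Phase-to-time mapping inside a chosen state picks the in-state
sample circularly nearest the drawn phase (earliest on ties), and surrogate
states must be at least twice the analysis window long so the windows fit.

Pre/post comparisons use the paired Wilcoxon signed-rank test (one-tailed
for the directional question), p-values across cells are corrected with the
Benjamini–Hochberg step-up procedure, and per-cell outcomes are combined
with the exact binomial upper tail `P(X ≥ k | n, p0 = 0.05)`. When counting
`m` significant cells the caller decides which `k` to pass; passing
`k = m + 1` corresponds to asking how surprising it is to observe *more
than* m − 1 successes; it is the convention behind the population p-values
asserted in the tests. Normalized variations express
pre/post rates as percentage deviations from the overall mean
surrogate-triggered rate. No causal claim follows from these statistics
alone; the module reproduces the statistical dependency analysis only.

## Evoked down-to-up transition latency

The illumination artifact (a brief ~4-ms polarization at light onset) is
corrected by subtracting the across-trial mean of artifact-only trials
(those without a sustained derivative crossing between 20 and 30 ms after
onset — the lower bound clears the artifact's own smoothed span) and
smoothing with a 14-ms moving average, all inside a 60-ms window centered
on each onset; everything outside the window is untouched.

Putative down states are samples where the beta/gamma evidence (10-ms RMS
frame for this analysis) lies below a threshold: the overall median by
default, with the full-width-half-maximum of the first distribution peak
and `μ + σ` of the lower component of a two-Gaussian fit as alternatives —
the three give closely similar latency results on synthetic sessions, which
the test suite checks. Below-threshold dips shorter than 100 ms (the
pipeline's minimum state duration) are discarded. The control-condition
threshold is deliberately reusable on post-manipulation recordings via the
`threshold` argument.

For each onset inside a putative down interval, the mean `μ` and SD `σ` of
the LFP temporal derivative are taken over that interval, and the latency
is the time from onset to the first **sustained** crossing below
`T = μ − kσ` (k = 4 for evoked, k = 2 for spontaneous transitions, whose
slopes are slower). Three numerical choices:

* The derivative is computed on a 14-ms moving-averaged LFP. The raw
  sample-to-sample derivative at 1 kHz is dominated by the `[10, 51]` Hz
  noise; the down-to-up deflection unfolds over tens of milliseconds and
  survives the smoothing intact.
* A crossing must persist for 10 ms. Genuine deflections hold the
  derivative below threshold for tens of milliseconds; brief noise
  excursions — frequent at k = 2 — do not. Without this rule spontaneous
  latencies collapse to noise first-passage times.
* The crossing is searched forward from the onset rather than only inside
  the putative down interval (the power-evidence interval necessarily ends
  *before* the deflection it is announcing), with a horizon: the
  illumination duration (0.5 s) for evoked transitions — a transition
  after light offset cannot be attributed to the light — and 2 s for
  spontaneous ones. Trials without a qualifying crossing are censored and
  counted, not imputed.

Spontaneous latencies use surrogate onsets on a periodic grid (default
0.5 s; results are insensitive to the grid phase, which is tested)
restricted to spontaneous activity — at least 50 ms before each onset and
550 ms after each offset. The summary is the ratio of mean uncensored
evoked latency to mean uncensored spontaneous latency.

The confirmatory linear mixed-effects analysis of latencies (fixed effects
for treatment, stimulation and their interaction; per-animal random
intercepts) is not re-implemented: the pipeline exports a tidy per-trial
table (`onset`, state at onset, `latency`, censoring flag) suitable for
`lme4::lmer(latency ~ treatment * stimulation + (1 | animal:treatment) + (1 | animal:stimulation), ...)`
or any equivalent tool.

## The synthetic-data generator

`synth_params()` defines the study conditions; the defaults are fixed from
the summary statistics such experiments report where available, and
otherwise from what is typical for urethane-anesthetized thalamo-cortical
recordings:

* Semi-Markov up/down alternation, gamma-distributed durations (mean 0.4 s
  up / 0.6 s down, shape 4, truncated at 100 ms), giving about one cycle
  per second — inside the 0.2–1 Hz slow-oscillation range. A gamma
  semi-Markov model keeps duration variability meaningful without
  committing to a mechanism.
* LFP: ±1 (a.u.) baseline, depth-positive in down states, raised-cosine
  ramps of 50 ms at transitions (the labeled boundary is the ramp
  midpoint), `[10, 51]` Hz noise with SD 0.15 in up states and ratio 3
  between states, 1/f background with SD 0.03.
* PV spikes: 8 spikes/s in up, 0.3 in down (≈3.4 spikes/s overall), von
  Mises phase gain κ = 1.4 at 188°; VPM: 23 up / 1.2 down (≈10 spikes/s
  overall, active in roughly half of down states), κ = 0.6 at 191°. The
  phase gain is normalized per state so the configured state rates are the
  realized rates; spike times come from thinning the piecewise intensity,
  which is exact and seedable.
* Optional causal coupling: each VPM spike in a down state adds a Gaussian
  intensity bump to the PV train (lag 20 ms, SD 5 ms); the gain is the
  expected number of extra PV spikes per VPM down-state spike (0 =
  uncoupled; 0.5 is used as the "coupled" condition in tests).
* Voltage traces: stereotyped biphasic waveforms (positive-dominant
  juxtasomal, negative-dominant multi-unit; peak-to-trough < 3 ms;
  principal peak at the spike time) on Gaussian noise, amplitudes 10× and
  12× the noise SD.
* Optogenetic sessions: 5-s trials, one onset each at a random position;
  onsets falling in a true down state insert a transition at
  onset + latency, with latency drawn from N(0.11, 0.02²) s in control
  mode. Muscimol-like mode lengthens down durations (×1.6), suppresses the
  down-state PV rate (×0.2) and draws latencies from N(0.25, 0.05²) s —
  the means follow reported group means; the trial-level SD of the
  muscimol mode is a stand-in, since the reported across-animal spread
  cannot serve as a within-session trial SD. A 4-ms half-cosine light
  artifact is added at every onset.

What the generator does **not** emulate: animal-to-animal variability
structure beyond its configurable parameters, biophysical (conductance)
dynamics, electrode drift or movement artifacts, non-stationarity of
anesthesia depth, and realistic spike-waveform diversity or overlap
sorting. Passing tests on this generator therefore demonstrate the
correctness and calibration of the *analysis machinery* under matched
assumptions — not performance guarantees on any particular real recording.
One concrete example of the gap: the generated delta phase is much more
tightly locked to state boundaries than real phases are, which makes
boundary-precision results on synthetic data optimistic and slightly
distorts edge bins of phase-trimmed relative-time histograms.

## Degenerate inputs and edge behavior

All-zero or constant traces are rejected where they would make a statistic
meaningless (phase extraction, evidence normalization, mixture fitting).
Threshold ties go to the indeterminate state. Surrogate construction fails
loudly when the silent-state pool cannot hold the required spikes. Trials
whose onset misses a putative down state are excluded (and flagged), not
silently dropped. Writers refuse overlapping segmentations. Every
stochastic operation takes an explicit seed, and identical seeds give
identical outputs.

## Problem sizes used in validation

The packaged checks run at deliberately moderate scale, chosen to exercise
each method's asymptotics without waste: 600-s sessions (five seeds) for
segmentation accuracy, 60-s traces for spike detection, 120-s sessions for
phase and surrogate analyses (200 null runs for calibration, 50 for power),
and 50-trial optogenetic sessions (twenty seed pairs for the
control-vs-muscimol direction). The acceptance script mirrors these sizes.
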